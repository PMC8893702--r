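# Example task configuration (all keys optional; defaults shown)
taskName: 2context
shortInterval: 3
longInterval: 6
contextLevels: [0.75, 0.25]
goEnabled: true
contextMode: persistent
stimDuration: 0.5
baselineRange: [0.2, 0.6]
postInterval: 0.2
dt: 0.02
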