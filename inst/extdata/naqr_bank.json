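{"items":[{"id":"naq1","delta":-2.21},{"id":"naq2","delta":-0.79},{"id":"naq3","delta":-0.24},{"id":"naq4","delta":-0.09},{"id":"naq5","delta":-0.9},{"id":"naq6","delta":0.61},{"id":"naq7","delta":-0.19},{"id":"naq8","delta":-1.5},{"id":"naq9","delta":1.35},{"id":"naq10","delta":1.65},{"id":"naq11","delta":-0.68},{"id":"naq12","delta":-0.57},{"id":"naq13","delta":-0.33},{"id":"naq14","delta":-0.61},{"id":"naq15","delta":0.46},{"id":"naq16","delta":0.04},{"id":"naq17","delta":0.2},{"id":"naq18","delta":-0.41},{"id":"naq19","delta":0.37},{"id":"naq20","delta":1.09},{"id":"naq21","delta":0.18},{"id":"naq22","delta":2.56}],"thresholds":[-3.39,-0.55,1.11,2.83],"n_categories":5}
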