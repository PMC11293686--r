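{"pixelSizeUm":0.31,"axes":[{"id":"v1","points":[[32,12],[32,288]],"zSlice":null},{"id":"v2","points":[[14,40],[22,120],[30,210]],"zSlice":null}]}
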