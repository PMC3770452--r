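Group	AA	AB	BB	Total
Case	55	83	50	188
Control	24	42	39	105
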