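printed	corrected
TXRND2	TXNRD2
CHUCK	CHUK
NFKB1A	NFKBIA
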