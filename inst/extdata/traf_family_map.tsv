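gene	family
TRAF1	TRAF
TRAF2	TRAF
TRAF3	TRAF
TRAF4	TRAF
TRAF5	TRAF
TRAF6	TRAF
TRAF7	TRAF
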