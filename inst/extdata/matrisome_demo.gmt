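collagens	na	COL1	COL2	COL3	COL4	COL5	COL6
glycoproteins	na	GP1	GP2	GP3	GP4	GP5	GP6
proteoglycans	na	PG1	PG2	PG3	PG4	PG5	PG6
ECM-regulators	na	REG1	REG2	REG3	REG4	REG5	REG6
secreted-factors	na	SF1	SF2	SF3	SF4	SF5	SF6
ECM-affiliated	na	AFF1	AFF2	AFF3	AFF4	AFF5	AFF6
matrisome	union of the six category sets	COL1	COL2	COL3	COL4	COL5	COL6	GP1	GP2	GP3	GP4	GP5	GP6	PG1	PG2	PG3	PG4	PG5	PG6	REG1	REG2	REG3	REG4	REG5	REG6	SF1	SF2	SF3	SF4	SF5	SF6	AFF1	AFF2	AFF3	AFF4	AFF5	AFF6
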