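compound_name	molecular_target	chemical_basis	length	target_accessions
Corticotropin	MC receptors	Native	39	Q01726;Q01718;P41968;P32245;P33032
Calcitonin (salmon)	Calcitonin receptor	Native	32	P30988
Tetracosactide	MC receptors	Native	24	Q01726;Q01718;P41968;P32245;P33032
Calcitonin (human)	Calcitonin receptor	Native	32	Q16602
Carperitide	NPR-A	Native	28	P16066;P20594;P17342
Bivalirudin	Thrombin	Analog	20	P00734
Nesiritide	NPR-A	Native	32	P16066;P20594;P17342
Pramlintide	Calcitonin receptor	Analog	37	Q16602
Exenatide	GLP-1 receptor	Native	39	P43220
Liraglutide	GLP-1 receptor	Analog	32	P43220
Tesamorelin	GHRH receptor	Analog	44	Q02643
Teduglutide	GLP-2 receptor	Analog	33	O95838
Lixisenatide	GLP-1 receptor	Analog	44	P43220
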