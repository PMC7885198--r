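Nc1ccc(O)cc1O dha
Nc1ccc(O)cc1 aminophenol_4
Nc1cccc(O)c1 aminophenol_3
Nc1ccccc1O aminophenol_2
Oc1ccc(O)cc1 hydroquinone
Oc1ccccc1O catechol
Oc1cccc(O)c1 resorcinol
Nc1ccc(N)cc1 phenylenediamine_14
Nc1ccccc1N phenylenediamine_12
Nc1ccccc1 aniline
Oc1ccccc1 phenol
Cc1ccc(N)cc1 toluidine_4
Cc1ccccc1N toluidine_2
Cc1ccc(O)cc1 cresol_4
Cc1ccc(N)c(O)c1 amino_cresol
Nc1ccc(O)c(O)c1 dihydroxyaniline_34
Nc1cc(O)ccc1O aminophenol_iso
COc1ccc(N)cc1 anisidine_4
COc1ccccc1N anisidine_2
Nc1ccc(Cl)cc1 chloroaniline_4
Oc1ccc(Cl)cc1 chlorophenol_4
Nc1ccc(C)c(C)c1 xylidine
Oc1ccc(O)c(C)c1 methyl_hydroquinone
Nc1ccc(N)c(O)c1 diamino_phenol
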