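# Built-in lipid species library. Areas are literature approximations in
# square Angstrom; charges are formal headgroup charges at pH 7.5 assuming
# full ionization (cardiolipins dianionic, PG monoanionic).
name	formal_charge	cross_sectional_area_A2
POPC	0	70
POPG	-1	70
TOCL	-2	130
MLCL	-2	110
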