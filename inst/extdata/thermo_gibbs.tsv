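# Standard Gibbs energies of formation, fixed reference condition 310.15 K, 1 bar.
# Basis species: aqueous amino acids, liquid H2O, gaseous O2, aqueous proton (0 by convention).
# Residue groups = aqueous amino acid minus H2O (condensation-energy-neutral approximation);
# 25 C literature values used at the reference condition. See the methods vignette.
species	kind	formula	G0_Jmol	source
Cys	basis	C3H7NO2S	-340100	AH97-compiled
Glu	basis	C5H9NO4	-723800	AH97-compiled
Gln	basis	C5H10N2O3	-529900	AH97-compiled
H2O	basis	H2O	-237180	CODATA
O2	basis	O2	0	convention-gas
H+	basis	H+1	0	convention-proton
Ala	residue	C3H5NO	-133820	AH97-compiled-minus-H2O
Arg	residue	C6H12N4O	-3020	AH97-compiled-minus-H2O
Asn	residue	C4H6N2O2	-288720	AH97-compiled-minus-H2O
Asp	residue	C4H5NO3	-484120	AH97-compiled-minus-H2O
Cys	residue	C3H5NOS	-102920	AH97-compiled-minus-H2O
Gln	residue	C5H8N2O2	-292720	AH97-compiled-minus-H2O
Glu	residue	C5H7NO3	-486620	AH97-compiled-minus-H2O
Gly	residue	C2H3NO	-133620	AH97-compiled-minus-H2O
His	residue	C6H7N3O	34380	AH97-compiled-minus-H2O
Ile	residue	C6H11NO	-106720	AH97-compiled-minus-H2O
Leu	residue	C6H11NO	-115120	AH97-compiled-minus-H2O
Lys	residue	C6H12N2O	-98920	AH97-compiled-minus-H2O
Met	residue	C5H9NOS	-13420	additivity-estimate-minus-H2O
Phe	residue	C9H9NO	30080	AH97-compiled-minus-H2O
Pro	residue	C5H7NO	-59420	AH97-compiled-minus-H2O
Ser	residue	C3H5NO2	-273720	AH97-compiled-minus-H2O
Thr	residue	C4H7NO2	-277420	AH97-compiled-minus-H2O
Trp	residue	C11H10N2O	124580	AH97-compiled-minus-H2O
Tyr	residue	C9H9NO2	-148520	AH97-compiled-minus-H2O
Val	residue	C5H9NO	-119720	AH97-compiled-minus-H2O
terminus	terminus	H2O	-237180	CODATA
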