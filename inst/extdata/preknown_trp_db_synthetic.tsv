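name	composition	class	plausible	source	steps
Oxidation	O	Reactive species	TRUE	preknown	1
Dihydroxylation	O(2)	Reactive species	TRUE	preknown	1
Trioxidation	O(3)	Reactive species	TRUE	preknown	1
Tetraoxidation	O(4)	Reactive species	TRUE	preknown	1
Trp->Kynurenine	C(-1)O	Reactive species	TRUE	preknown	1
Trp->Hydroxykynurenine	C(-1)O(2)	Reactive species	TRUE	preknown	1
Trp->Oxokynurenine	C(-1)O(3)	Reactive species	TRUE	preknown	1
Nitration	H(-1)NO(2)	Reactive species	TRUE	preknown	1
Nitrosylation	H(-1)NO	Reactive species	TRUE	preknown	1
Dinitration	H(-2)N(2)O(4)	Reactive species	TRUE	preknown	1
Dehydrogenation	H(-2)	Reactive species	TRUE	preknown	1
Tryptophandione	H(-2)O(2)	Reactive species	TRUE	preknown	1
Hydroxytryptophandione	H(-2)O(3)	Reactive species	TRUE	preknown	1
Dihydroxytryptophandione	H(-2)O(4)	Reactive species	TRUE	preknown	1
Chlorination	H(-1)Cl	Reactive species	TRUE	preknown	1
Dichlorination	H(-2)Cl(2)	Reactive species	TRUE	preknown	1
Bromination	H(-1)Br	Reactive species	TRUE	preknown	1
Nitrohydroxylation	H(-1)NO(3)	Reactive species	TRUE	preknown	1
Carbonylation	H(-2)O	Reactive species	TRUE	preknown	1
Hydroxymethylation	CH(2)O	Reactive species	TRUE	preknown	1
Cysteinylation	C(3)H(5)NOS	Chemical derivative	TRUE	preknown	1
Methylation	CH(2)	Chemical derivative	TRUE	preknown	1
Dimethylation	C(2)H(4)	Chemical derivative	TRUE	preknown	1
Formylation	CO	Chemical derivative	TRUE	preknown	1
Acetylation	C(2)H(2)O	Chemical derivative	TRUE	preknown	1
Lactoylation	C(3)H(4)O(2)	Chemical derivative	TRUE	preknown	1
Phosphorylation	HO(3)P	Chemical derivative	TRUE	preknown	1
Hexose adduct	C(6)H(10)O(5)	Chemical derivative	TRUE	preknown	1
Hexosamine adduct	C(6)H(11)NO(4)	Chemical derivative	TRUE	preknown	1
Malonylation	C(3)H(2)O(3)	Chemical derivative	TRUE	preknown	1
Succinylation	C(4)H(4)O(3)	Chemical derivative	TRUE	preknown	1
Crotonylation	C(4)H(4)O	Chemical derivative	TRUE	preknown	1
Butyrylation	C(4)H(6)O	Chemical derivative	TRUE	preknown	1
Glutathionylation	C(10)H(15)N(3)O(6)S	Chemical derivative	TRUE	preknown	1
Homocysteinylation	C(4)H(7)NOS	Chemical derivative	TRUE	preknown	1
Pyridoxal phosphate adduct	C(8)H(8)NO(5)P	Chemical derivative	FALSE	preknown	1
Heme adduct	C(34)H(32)N(4)O(4)Fe	Chemical derivative	FALSE	preknown	1
Carbamidomethylation	C(2)H(3)NO	Artefact	TRUE	preknown	1
Carbamidomethylated DTT	H(11)C(6)NO(3)S(2)	Artefact	TRUE	preknown	1
DTT adduct	C(4)H(8)O(2)S(2)	Artefact	TRUE	preknown	1
Carbamylation	CHNO	Artefact	TRUE	preknown	1
Deamidation	H(-1)N(-1)O	Artefact	TRUE	preknown	1
Ammonia loss	H(-3)N(-1)	Artefact	TRUE	preknown	1
Trp->Gly	C(-9)H(-7)N(-1)	AA substitution	TRUE	preknown	1
Trp->Ala	C(-8)H(-5)N(-1)	AA substitution	TRUE	preknown	1
Trp->Ser	C(-8)H(-5)N(-1)O	AA substitution	TRUE	preknown	1
Trp->Pro	C(-6)H(-3)N(-1)	AA substitution	TRUE	preknown	1
Trp->Val	C(-6)H(-1)N(-1)	AA substitution	TRUE	preknown	1
Trp->Thr	C(-7)H(-3)N(-1)O	AA substitution	TRUE	preknown	1
Trp->Cys	C(-8)H(-5)N(-1)S	AA substitution	TRUE	preknown	1
Trp->Leu	C(-5)HN(-1)	AA substitution	TRUE	preknown	1
Trp->Ile	C(-5)HN(-1)	AA substitution	TRUE	preknown	1
Trp->Asn	C(-7)H(-4)O	AA substitution	TRUE	preknown	1
Trp->Asp	C(-7)H(-5)N(-1)O(2)	AA substitution	TRUE	preknown	1
Trp->Gln	C(-6)H(-2)O	AA substitution	TRUE	preknown	1
Trp->Lys	C(-5)H(2)	AA substitution	TRUE	preknown	1
Trp->Glu	C(-6)H(-3)N(-1)O(2)	AA substitution	TRUE	preknown	1
Trp->Met	C(-6)H(-1)N(-1)S	AA substitution	TRUE	preknown	1
Trp->His	C(-5)H(-3)N	AA substitution	TRUE	preknown	1
Trp->Phe	C(-2)H(-1)N(-1)	AA substitution	TRUE	preknown	1
Trp->Arg	C(-5)H(2)N(2)	AA substitution	TRUE	preknown	1
Trp->Tyr	C(-2)H(-1)N(-1)O	AA substitution	TRUE	preknown	1
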