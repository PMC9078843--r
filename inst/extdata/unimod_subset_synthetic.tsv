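name	composition	class	plausible	source	steps
Oxidation	O	Reactive species	TRUE	unimod	1
Dihydroxylation	O(2)	Reactive species	TRUE	unimod	1
Trioxidation	O(3)	Reactive species	TRUE	unimod	1
Tetraoxidation	O(4)	Reactive species	TRUE	unimod	1
Dehydrogenation	H(-2)	Reactive species	TRUE	unimod	1
Didehydrogenation	H(-4)	Reactive species	TRUE	unimod	1
Nitration	H(-1)NO(2)	Reactive species	TRUE	unimod	1
Nitrosylation	H(-1)NO	Reactive species	TRUE	unimod	1
Carbonylation	H(-2)O	Reactive species	TRUE	unimod	1
Chlorination	H(-1)Cl	Reactive species	TRUE	unimod	1
Bromination	H(-1)Br	Reactive species	TRUE	unimod	1
Methylation	CH(2)	Chemical derivative	TRUE	unimod	1
Dimethylation	C(2)H(4)	Chemical derivative	TRUE	unimod	1
Trimethylation	C(3)H(6)	Chemical derivative	TRUE	unimod	1
Formylation	CO	Chemical derivative	TRUE	unimod	1
Acetylation	C(2)H(2)O	Chemical derivative	TRUE	unimod	1
Propionylation	C(3)H(4)O	Chemical derivative	TRUE	unimod	1
Butyrylation	C(4)H(6)O	Chemical derivative	TRUE	unimod	1
Crotonylation	C(4)H(4)O	Chemical derivative	TRUE	unimod	1
Malonylation	C(3)H(2)O(3)	Chemical derivative	TRUE	unimod	1
Succinylation	C(4)H(4)O(3)	Chemical derivative	TRUE	unimod	1
Glutarylation	C(5)H(6)O(3)	Chemical derivative	TRUE	unimod	1
Benzoylation	C(7)H(4)O	Chemical derivative	TRUE	unimod	1
Phosphorylation	HO(3)P	Chemical derivative	TRUE	unimod	1
Sulfation	O(3)S	Chemical derivative	TRUE	unimod	1
Sulfhydration	S	Chemical derivative	TRUE	unimod	1
Carbamylation	CHNO	Artefact	TRUE	unimod	1
Carbamidomethylation	C(2)H(3)NO	Artefact	TRUE	unimod	1
Carboxymethylation	C(2)H(2)O(2)	Artefact	TRUE	unimod	1
Deamidation	H(-1)N(-1)O	Artefact	TRUE	unimod	1
Ammonia loss	H(-3)N(-1)	Artefact	TRUE	unimod	1
Water loss	H(-2)O(-1)	Artefact	TRUE	unimod	1
Ammonium replacement of proton	H(3)N	Chemical derivative	TRUE	unimod	1
Sodium replacement of proton	H(-1)Na	Artefact	TRUE	unimod	1
Potassium replacement of proton	H(-1)K	Artefact	TRUE	unimod	1
Lactoylation	C(3)H(4)O(2)	Chemical derivative	TRUE	unimod	1
Pyruvoylation	C(3)H(2)O(2)	Chemical derivative	TRUE	unimod	1
Glyoxal adduct	C(2)H(2)O(2)	Reactive species	TRUE	unimod	1
Methylglyoxal adduct	C(3)H(4)O(2)	Reactive species	TRUE	unimod	1
HNE adduct	C(9)H(16)O(2)	Reactive species	TRUE	unimod	1
MDA adduct	C(3)H(2)O	Reactive species	TRUE	unimod	1
Acrolein adduct	C(3)H(4)O	Reactive species	TRUE	unimod	1
Crotonaldehyde adduct	C(4)H(6)O	Reactive species	TRUE	unimod	1
Hexose adduct	C(6)H(10)O(5)	Chemical derivative	TRUE	unimod	1
Hexosamine adduct	C(6)H(11)NO(4)	Chemical derivative	TRUE	unimod	1
HexNAc adduct	C(8)H(13)NO(5)	Chemical derivative	TRUE	unimod	1
Pentose adduct	C(5)H(8)O(4)	Chemical derivative	TRUE	unimod	1
Deoxyhexose adduct	C(6)H(10)O(4)	Chemical derivative	TRUE	unimod	1
Glucuronyl adduct	C(6)H(8)O(6)	Chemical derivative	TRUE	unimod	1
Glycinylation	C(2)H(3)NO	Chemical derivative	TRUE	unimod	1
Alanylation	C(3)H(5)NO	Chemical derivative	TRUE	unimod	1
Serylation	C(3)H(5)NO(2)	Chemical derivative	TRUE	unimod	1
Prolylation	C(5)H(7)NO	Chemical derivative	TRUE	unimod	1
Valylation	C(5)H(9)NO	Chemical derivative	TRUE	unimod	1
Threonylation	C(4)H(7)NO(2)	Chemical derivative	TRUE	unimod	1
Cysteinylation	C(3)H(5)NOS	Chemical derivative	TRUE	unimod	1
Leucylation	C(6)H(11)NO	Chemical derivative	TRUE	unimod	1
Asparaginylation	C(4)H(6)N(2)O(2)	Chemical derivative	TRUE	unimod	1
Aspartylation	C(4)H(5)NO(3)	Chemical derivative	TRUE	unimod	1
Glutaminylation	C(5)H(8)N(2)O(2)	Chemical derivative	TRUE	unimod	1
Lysylation	C(6)H(12)N(2)O	Chemical derivative	TRUE	unimod	1
Glutamylation	C(5)H(7)NO(3)	Chemical derivative	TRUE	unimod	1
Methionylation	C(5)H(9)NOS	Chemical derivative	TRUE	unimod	1
Histidinylation	C(6)H(7)N(3)O	Chemical derivative	TRUE	unimod	1
Phenylalanylation	C(9)H(9)NO	Chemical derivative	TRUE	unimod	1
Arginylation	C(6)H(12)N(4)O	Chemical derivative	TRUE	unimod	1
Tyrosylation	C(9)H(9)NO(2)	Chemical derivative	TRUE	unimod	1
Tryptophanylation	C(11)H(10)N(2)O	Chemical derivative	TRUE	unimod	1
Glycylglycylation	C(4)H(6)N(2)O(2)	Chemical derivative	TRUE	unimod	1
Myristoylation	C(14)H(26)O	Chemical derivative	TRUE	unimod	1
Palmitoylation	C(16)H(30)O	Chemical derivative	TRUE	unimod	1
Stearoylation	C(18)H(34)O	Chemical derivative	TRUE	unimod	1
Octanoylation	C(8)H(14)O	Chemical derivative	TRUE	unimod	1
Decanoylation	C(10)H(18)O	Chemical derivative	TRUE	unimod	1
Hydroxydecanoylation	C(10)H(18)O(2)	Chemical derivative	TRUE	unimod	1
Docosahexaenoylation	C(22)H(30)O	Chemical derivative	TRUE	unimod	1
Oxocholoylation	C(24)H(36)O(4)	Chemical derivative	TRUE	unimod	1
Lipoylation	C(8)H(12)OS(2)	Chemical derivative	TRUE	unimod	1
Farnesylation	C(15)H(24)	Chemical derivative	TRUE	unimod	1
Geranylgeranylation	C(20)H(32)	Chemical derivative	TRUE	unimod	1
Biotinylation	C(10)H(14)N(2)O(2)S	Chemical derivative	TRUE	unimod	1
Pyridoxal phosphate adduct	C(8)H(8)NO(5)P	Chemical derivative	TRUE	unimod	1
Glutathionylation	C(10)H(15)N(3)O(6)S	Chemical derivative	TRUE	unimod	1
Homocysteinylation	C(4)H(7)NOS	Chemical derivative	TRUE	unimod	1
Spermidine adduct	C(7)H(17)N(3)	Chemical derivative	TRUE	unimod	1
Putrescine adduct	C(4)H(10)N(2)	Chemical derivative	TRUE	unimod	1
Ethanolamine adduct	C(2)H(5)NO	Chemical derivative	TRUE	unimod	1
Thiobutyroylation	C(4)H(6)OS	Chemical derivative	TRUE	unimod	1
Citrylation	C(6)H(6)O(6)	Chemical derivative	TRUE	unimod	1
Hydroxybutyrylation	C(4)H(6)O(2)	Chemical derivative	TRUE	unimod	1
Hydroxyisobutyrylation	C(4)H(6)O(2)	Chemical derivative	TRUE	unimod	1
Levuglandinyl lactam adduct	C(20)H(28)O(4)	Chemical derivative	TRUE	unimod	1
Methylation then oxidation	CH(2)O	Chemical derivative	TRUE	unimod	2
Formylation then oxidation	CO(2)	Chemical derivative	TRUE	unimod	2
Hydroxylation with hydrogen loss	OH(-1)	Reactive species	FALSE	unimod	1
Dioxidation with dehydrogenation	H(-2)O(2)	Reactive species	TRUE	unimod	2
Cyanylation	CH(-1)N	Artefact	TRUE	unimod	1
Iron replacement of two protons	H(-2)Fe	Artefact	FALSE	unimod	1
Ethylation	C(2)H(4)	Chemical derivative	TRUE	unimod	1
Propionamidation	C(3)H(5)NO	Artefact	TRUE	unimod	1
Pyrophosphorylation	H(2)O(6)P(2)	Chemical derivative	TRUE	unimod	1
Adenylylation	C(10)H(12)N(5)O(6)P	Chemical derivative	TRUE	unimod	1
Ubiquitin remnant	C(4)H(6)N(2)O(2)	Chemical derivative	TRUE	unimod	1
Nicotinoylation	C(6)H(3)NO	Chemical derivative	TRUE	unimod	1
Malondialdehyde acetal	C(3)H(4)O	Reactive species	TRUE	unimod	1
Semiquinone adduct	C(6)H(2)O(2)	Reactive species	TRUE	unimod	1
Dopamine quinone adduct	C(8)H(7)NO(2)	Reactive species	TRUE	unimod	1
Ascorbylation	C(6)H(6)O(6)	Chemical derivative	TRUE	unimod	1
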