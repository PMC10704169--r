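lipid_class	adduct	kind	formula	mz	label	rel_intensity
PG	*	neutral_loss	C3H7O5P		loss of glycerophosphate head	60
Me-PGP	*	neutral_loss	C4H10O8P2		loss of methyl-PGP head	60
PGS	*	neutral_loss	C3H7O8PS		loss of sulfated glycerophosphate head	60
PA	*	neutral_loss	HO3P		loss of phosphate head	60
PE	*	neutral_loss	C2H6NO3P		loss of phosphoethanolamine head	60
PI	*	neutral_loss	C6H11O8P		loss of phosphoinositol head	60
Gly-PG	*	neutral_loss	C9H17O10P		loss of glycosyl-PG head	60
MGD	*	neutral_loss	C6H10O5		hexose loss	40
DGD	*	neutral_loss	C6H10O5		hexose loss	40
TGD	*	neutral_loss	C6H10O5		hexose loss	40
S-MGD	*	neutral_loss	C6H10O5		hexose loss	40
S-DGD	*	neutral_loss	C6H10O5		hexose loss	40
2S-DGD	*	neutral_loss	C6H10O5		hexose loss	40
S-Gly-AHH	*	neutral_loss	C6H10O5		hexose loss	40
2S-Gly-AHH	*	neutral_loss	C6H10O5		hexose loss	40
Gly-PG	*	neutral_loss	C6H10O5		hexose loss	35
MGD-PA	*	neutral_loss	C6H10O5		hexose loss	40
DGD-PA	*	neutral_loss	C6H10O5		hexose loss	40
TGD-PA	*	neutral_loss	C6H10O5		hexose loss	40
S-DGD-PA	*	neutral_loss	C6H10O5		hexose loss	40
S-MGD	*	neutral_loss	O3S		sulfate loss	30
S-DGD	*	neutral_loss	O3S		sulfate loss	30
2S-DGD	*	neutral_loss	O3S		sulfate loss	30
S-Gly-AHH	*	neutral_loss	O3S		sulfate loss	30
2S-Gly-AHH	*	neutral_loss	O3S		sulfate loss	30
S-DGD-PA	*	neutral_loss	O3S		sulfate loss	30
BPG	*	neutral_loss	C3H8O8P2		loss of glycerol diphosphate bridge	50
MGD-PA	*	neutral_loss	HO3P		phosphate loss	30
DGD-PA	*	neutral_loss	HO3P		phosphate loss	30
TGD-PA	*	neutral_loss	HO3P		phosphate loss	30
S-DGD-PA	*	neutral_loss	HO3P		phosphate loss	30
AR	[M+H]+	neutral_loss	C20H40		phytanyl chain loss	50
AR	[M+NH4]+	neutral_loss	C20H40		phytanyl chain loss	50
PG	[M+H]+	neutral_loss	C20H40		phytanyl chain loss	45
Me-PGP	[M+H]+	neutral_loss	C20H40		phytanyl chain loss	45
S-DGD	[M+H]+	neutral_loss	C20H40		phytanyl chain loss	45
DGD	[M+H]+	neutral_loss	C20H40		phytanyl chain loss	45
PI	*	diagnostic_ion		261.038	tentative PI head-group ion	80
S-MGD	*	diagnostic_ion	C6H10O8S		sulfohexose head ion	35
S-DGD	*	diagnostic_ion	C6H10O8S		sulfohexose head ion	35
2S-DGD	*	diagnostic_ion	C6H10O8S		sulfohexose head ion	35
S-DGD-PA	*	diagnostic_ion	C6H10O8S		sulfohexose head ion	35
S-Gly-AHH	*	diagnostic_ion	C6H13NO5		glycosyl-aminohexanehexaol head ion	35
2S-Gly-AHH	*	diagnostic_ion	C6H13NO5		glycosyl-aminohexanehexaol head ion	35
PE	*	diagnostic_ion	C2H6NO3P		phosphoethanolamine head ion	35
MGD	*	diagnostic_ion	C6H10O5		hexose oxocarbenium	30
DGD	*	diagnostic_ion	C6H10O5		hexose oxocarbenium	30
TGD	*	diagnostic_ion	C6H10O5		hexose oxocarbenium	30
*	[M+NH4]+	neutral_loss	H3N		ammonia loss	45
*	[M+Na]+	unsat_chain_loss			intact unsaturated chain loss	70
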