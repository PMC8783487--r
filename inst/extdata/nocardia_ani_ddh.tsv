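# Published pairwise ANI and dDDH percentages between Nocardia alni ncl2^T
# (DSM 110931^T) and the type strains of its closest phylogenomic
# neighbours. Inputs for the species-boundary classification.
species	strain	ddh_percent	ani_percent
N. aobensis	NBRC 100429T	22.4	77.9
N. casuarinae	BMG 51109T	23.0	78.9
N. cerradoensis	NBRC 101014T	22.4	77.8
N. jiangxiensis	NBRC 101359T	24.6	80.6
N. miyunensis	NBRC 108239T	24.9	80.7
N. nova	NBRC 15556T	22.4	77.9
N. pseudobrasiliensis	DSM 44290T	22.4	78.7
N. vaccinii	NBRC 15922T	24.4	80.2
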