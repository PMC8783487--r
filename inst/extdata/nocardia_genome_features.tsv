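# Published genome features of Nocardia alni ncl2^T (DSM 110931^T) and the
# type strains of its five reference neighbours. Inputs for the CDS-count
# versus genome-size regression.
genome	size_mbp	gc_percent	n_rrna	n_trna	n_cds	median_cds_len
N. alni ncl2T	9.9	67.0	12	49	8969	831
N. vaccinii	9.2	66.7	4	49	8502	816
N. miyunensis	10.5	66.9	4	49	9567	831
N. jiangxiensis	10.4	66.7	3	49	9695	822
N. casuarinae	8.8	68.9	9	56	7746	819
N. pseudobrasiliensis	8.4	67.3	8	51	7949	822
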