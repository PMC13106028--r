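study	stratum	n	n_wl	in_cosmo	in_baa	in_nhw
FHS	ALL	546	295	TRUE	FALSE	TRUE
MESA	ALL	452	160	TRUE	FALSE	FALSE
CHS	ALL	795	368	TRUE	FALSE	FALSE
JHS	ALL	104	45	TRUE	TRUE	FALSE
COPDGene	ALL	3097	1457	TRUE	FALSE	FALSE
COPDGene	NHW	2311	NA	FALSE	FALSE	TRUE
COPDGene	BAA	786	NA	FALSE	TRUE	FALSE
ECLIPSE	ALL	1888	590	TRUE	FALSE	TRUE
SPIROMICS	ALL	1234	389	TRUE	FALSE	FALSE
SPIROMICS	NHW	995	NA	FALSE	FALSE	TRUE
SPIROMICS	BAA	167	NA	FALSE	TRUE	FALSE
AllOfUs	ALL	8856	4287	TRUE	FALSE	FALSE
AllOfUs	NHW	5483	NA	FALSE	FALSE	TRUE
AllOfUs	BAA	2278	NA	FALSE	TRUE	FALSE
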