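ISG_synthetic	synthetic placeholder for an interferon-stimulated-gene panel	g0001	g0002	g0003	g0004	g0005	g0006	g0007	g0008	g0009	g0010
NFKB_synthetic	synthetic placeholder for an NF-kB target-gene panel	g0011	g0012	g0013	g0014	g0015	g0016	g0017	g0018	g0019	g0020	g0021	g0022	g0023	g0024	g0025
TEXH_synthetic	synthetic placeholder for a six-gene T-cell-exhaustion panel	g0026	g0027	g0028	g0029	g0030	g0031
APOPTOSIS_P53_synthetic	synthetic placeholder apoptosis/p53 pathway members	g0002	g0008	g0014	g0020	g0026	g0032	g0035	g0038
RLR_synthetic	synthetic placeholder RIG-I-like receptor pathway members	g0003	g0009	g0015	g0021	g0033	g0039
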