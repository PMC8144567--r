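context	SigS1	SigS2	SigS3	SigS4	SigS5
A[C>A]A	0.08778275	0	0	0	0
A[C>A]C	0	0.04299459	0	0.00241092	0
A[C>A]G	0	0	0	0	0
A[C>A]T	0.17102994	0	0.0009561	0	0
C[C>A]A	0	0.00052551	0.07637971	0	0
C[C>A]C	0.02437055	0.00352366	0	0	0
C[C>A]G	0	0	0	0	0
C[C>A]T	8.7e-06	0	0	0	0
G[C>A]A	0	0	0	0	0
G[C>A]C	0	0.06108511	0	0	0.11032884
G[C>A]G	0	0	0.01091351	0	0.00330224
G[C>A]T	0	0	0	0	0
T[C>A]A	0	0	0	0	0
T[C>A]C	0	0	0	0.01334262	0
T[C>A]G	0.07421505	0	0	0	0
T[C>A]T	0.00580843	0.00271489	0	0	0
A[C>G]A	0.00936163	0	0	0.01110632	0.00221385
A[C>G]C	0	0	0.04061797	0	0.03142053
A[C>G]G	0	0	0	0	0
A[C>G]T	0	0	0	0.00043534	0
C[C>G]A	0	0	0.00035588	0	0.10031705
C[C>G]C	0	0	0	0.02405911	0.33975926
C[C>G]G	0	0	0	0	0
C[C>G]T	0	0	0.02106046	0	0.01574304
G[C>G]A	0.04292208	0	0.00821307	0	0
G[C>G]C	0.00762974	0.07617023	0	0	0.00034678
G[C>G]G	0	0.01780897	0	0	0
G[C>G]T	0	0	0.02639585	0	0
T[C>G]A	0	0	0	3.1e-07	0
T[C>G]C	0	0	0	0.00033625	0
T[C>G]G	0	0	0	0	0
T[C>G]T	0	0	0	0.00598667	0
A[C>T]A	0	0.10519284	0	0	0
A[C>T]C	0	0	0	0.0217415	0
A[C>T]G	0	0	0.00595313	0	0
A[C>T]T	0	0.11432961	0	0	0
C[C>T]A	0	0	0	0	0
C[C>T]C	0	0.06251899	0	0.09444782	0.02427121
C[C>T]G	0	0	0	0	0
C[C>T]T	0.02517234	0	0	0	0
G[C>T]A	0	0	0	0	0.00847393
G[C>T]C	0	0	0	0	0.00278785
G[C>T]G	0.00627867	0	0	0	0
G[C>T]T	0	0.00422043	0	0	0
T[C>T]A	0	0	0.00377208	0	0.00079378
T[C>T]C	0	0	0	0	0
T[C>T]G	0	0	0.00188847	0	0
T[C>T]T	0	0.02009738	0	0.00692014	7.531e-05
A[T>A]A	0.01087508	0	0.0561682	0	0
A[T>A]C	0	0	0	0	0
A[T>A]G	0	0	0	0	0.10185699
A[T>A]T	0	0	0	0	0
C[T>A]A	0	0	0	0.03406214	0
C[T>A]C	0	0	0	0	0
C[T>A]G	0	0	0	0	0
C[T>A]T	0.01831137	0	0	0	0
G[T>A]A	0	0.00689897	0.03592186	0.04434339	0
G[T>A]C	0	0	0	0.00474703	0
G[T>A]G	0	0	0.31589489	0	0
G[T>A]T	0	0	0	0	0
T[T>A]A	4.982e-05	0	0	0	0.05880038
T[T>A]C	0.02872792	0	0	0	0
T[T>A]G	0	0	0	0	0
T[T>A]T	0.00722997	0	8.596e-05	3.02e-06	0
A[T>C]A	0	0.02598773	0	0.00178379	0
A[T>C]C	0	0	0.0661842	0	0
A[T>C]G	0	0.00478847	0	0	0.07331039
A[T>C]T	0.10322681	0.03109532	0	0	0
C[T>C]A	0.00245974	0	0.12800137	0.03978146	0
C[T>C]C	0	0	0	0	0.01232424
C[T>C]G	0	0.0009051	0	0	0
C[T>C]T	0.01834344	0	0	0	0
G[T>C]A	0	0.00884578	0	0	0
G[T>C]C	0	0	0	0	0.00510968
G[T>C]G	0	0	0	0	0
G[T>C]T	0.00473079	0	0.05834735	0	0
T[T>C]A	0	0	0	0	0
T[T>C]C	0	0	0	0.00473605	0.00383177
T[T>C]G	0	0	0	0	0.01470484
T[T>C]T	0.00342049	0	0	0.21668581	0
A[T>G]A	0	0.09026471	0	0	0
A[T>G]C	0.14373457	0	0	0	0
A[T>G]G	0	0	0.01908639	0	0
A[T>G]T	0	0	0.09793038	0.04244776	0
C[T>G]A	0	0	0	0	0
C[T>G]C	0	0.0097573	0.00733825	0	0
C[T>G]G	0	0	0	0	0
C[T>G]T	0	0	0.00175212	0.0042236	0
G[T>G]A	0.02579285	0.00067929	0.01276195	0	0
G[T>G]C	0	0	0	0.04127676	0.00226255
G[T>G]G	0	0.12285834	0.00402085	0	0.03671285
G[T>G]T	0	0	0	0	0
T[T>G]A	0	0.01512921	0	0.36507441	0.02714423
T[T>G]C	0	0	0	0	0.0241084
T[T>G]G	0.17851727	0	0	0.02004779	0
T[T>G]T	0	0.17160758	0	0	0
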