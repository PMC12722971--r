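# Synthetic generic radial dose function g(r) for a high-dose-rate
# Ir-192 point-source model (1D TG-43 formalism).  Values are a smooth
# generic curve shaped like published HDR Ir-192 consensus data, normalized
# to g(1 cm) = 1; they are a stand-in for a specific commissioned source
# and are intended for plan *comparison*, not absolute clinical dosimetry.
r_cm	g
0.1	0.990
0.25	0.994
0.5	0.997
0.75	0.999
1.0	1.000
1.5	1.001
2.0	1.001
3.0	0.999
4.0	0.993
5.0	0.983
6.0	0.970
7.0	0.952
8.0	0.930
9.0	0.903
10.0	0.872
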