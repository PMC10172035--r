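# RNA nearest-neighbor duplex parameters, dG37 in kcal/mol.
# Stack keys are the 5'XY3' dinucleotide of one strand paired with its
# Watson-Crick complement (3'X'Y'5'); complementary keys carry equal values
# (duplex strand symmetry). version 1
param	value
AA	-0.93
UU	-0.93
AU	-1.10
UA	-1.33
CU	-2.08
AG	-2.08
CA	-2.11
UG	-2.11
GU	-2.24
AC	-2.24
GA	-2.35
UC	-2.35
CG	-2.36
GG	-3.26
CC	-3.26
GC	-3.42
init	4.09
terminal_AU	0.45
gu_stack	-1.30
loop_penalty	4.00
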