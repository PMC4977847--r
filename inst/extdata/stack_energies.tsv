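# nearest-neighbor stack free energies, kcal/mol at 37C, v1
# pair1 = (miRNA base, target base) at step start, pair2 at step end (miRNA 5->3)
pair1	pair2	dg
AU	AU	-0.93
AU	CG	-2.24
AU	GC	-2.08
AU	GU	-1.3
AU	UA	-1.1
AU	UG	-1.3
CG	AU	-2.11
CG	CG	-3.26
CG	GC	-2.36
CG	GU	-1.3
CG	UA	-2.08
CG	UG	-1.3
GC	AU	-2.35
GC	CG	-3.42
GC	GC	-3.26
GC	GU	-1.3
GC	UA	-2.24
GC	UG	-1.3
GU	AU	-1.3
GU	CG	-1.3
GU	GC	-1.3
GU	GU	-0.5
GU	UA	-1.3
GU	UG	-0.5
UA	AU	-1.33
UA	CG	-2.35
UA	GC	-2.11
UA	GU	-1.3
UA	UA	-0.93
UA	UG	-1.3
UG	AU	-1.3
UG	CG	-1.3
UG	GC	-1.3
UG	GU	-0.5
UG	UA	-1.3
UG	UG	-0.5
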