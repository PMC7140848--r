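# Simplified nearest-neighbor RNA energy parameters, 37 C, kcal/mol.
# Sections:
#   stack     key = OUTER/INNER pair codes for the stack 5'-ab-3' / 3'-a'b'-5',
#             where OUTER = (a,a') and INNER = (b,b'). Watson-Crick values follow
#             the Turner nearest-neighbor set; every stack involving a G:U or U:G
#             pair is set to a single mild value (-0.50) as a deliberate
#             simplification.
#   hairpin   key = loop size (nt); initiation penalty. Sizes above the largest
#             listed are extrapolated as E(max) + 1.75 * RT * ln(n/max).
#   bulge     key = total unpaired nt on one strand; same extrapolation rule.
#   internal  key = total unpaired nt (both strands); same extrapolation rule.
#   multiloop keys init/branch/unpaired: affine multibranch-loop cost.
# No dangling ends, no coaxial stacking, no AU-end penalties: the model trades
# exactness of Turner energies for a compact, auditable table.
section	key	value
stack	AU/AU	-0.93
stack	AU/UA	-1.10
stack	AU/GC	-2.08
stack	AU/CG	-2.24
stack	UA/AU	-1.33
stack	UA/UA	-0.93
stack	UA/GC	-2.11
stack	UA/CG	-2.35
stack	GC/AU	-2.35
stack	GC/UA	-2.24
stack	GC/GC	-3.26
stack	GC/CG	-3.42
stack	CG/AU	-2.11
stack	CG/UA	-2.08
stack	CG/GC	-2.36
stack	CG/CG	-3.26
stack	AU/GU	-0.50
stack	AU/UG	-0.50
stack	UA/GU	-0.50
stack	UA/UG	-0.50
stack	GC/GU	-0.50
stack	GC/UG	-0.50
stack	CG/GU	-0.50
stack	CG/UG	-0.50
stack	GU/AU	-0.50
stack	GU/UA	-0.50
stack	GU/GC	-0.50
stack	GU/CG	-0.50
stack	GU/GU	-0.50
stack	GU/UG	-0.50
stack	UG/AU	-0.50
stack	UG/UA	-0.50
stack	UG/GC	-0.50
stack	UG/CG	-0.50
stack	UG/GU	-0.50
stack	UG/UG	-0.50
hairpin	3	5.40
hairpin	4	5.60
hairpin	5	5.70
hairpin	6	5.40
hairpin	7	6.00
hairpin	8	5.50
hairpin	9	6.40
bulge	1	3.80
bulge	2	2.80
bulge	3	3.20
bulge	4	3.60
bulge	5	4.00
bulge	6	4.40
internal	2	1.50
internal	3	1.60
internal	4	1.70
internal	5	2.00
internal	6	2.20
multiloop	init	3.40
multiloop	branch	0.40
multiloop	unpaired	0.00
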