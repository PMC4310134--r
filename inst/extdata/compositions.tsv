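# Elemental compositions (C H O N S P).  Cofactor pairs and the proton/
# electron pseudo-species are carbon-free carriers (C0): their elements
# cancel within each pair and they never enter a yield or DoR computation.
# biomass_ext carries the C-mol content of one biomass unit (40 C-mmol per
# gram dry weight at 48 % carbon by mass).
glc_ext	C6H12O6
glyc_ext	C3H8O3
fum_ext	C4H4O4
succ_ext	C4H6O4
ac_ext	C2H4O2
etoh_ext	C2H6O
lac_ext	C3H6O3
form_ext	CH2O2
co2_ext	CO2
h2_ext	H2
pyr_ext	C3H4O3
biomass_ext	C40
o2_ext	O2
e_ext	C0
g6p	C6H13O9P
f6p	C6H13O9P
fbp	C6H14O12P2
dhap	C3H7O6P
gap	C3H7O6P
bpg	C3H8O10P2
pg3	C3H7O7P
pg2	C3H7O7P
pep	C3H5O6P
pyr	C3H4O3
p6g	C6H13O10P
ru5p	C5H11O8P
x5p	C5H11O8P
r5p	C5H11O8P
s7p	C7H15O10P
e4p	C4H9O7P
accoa	C2H3O
cit	C6H8O7
icit	C6H8O7
akg	C5H6O5
succoa	C4H5O4
succ	C4H6O4
fum	C4H4O4
mal	C4H6O5
oaa	C4H4O5
glyc	C3H8O3
g3p	C3H9O6P
actp	C2H5O5P
ac	C2H4O2
etoh	C2H6O
acald	C2H4O
lac	C3H6O3
form	CH2O2
co2	CO2
h2	H2
o2	O2
atp	C0
adp	C0
nad	C0
nadh	C0
nadp	C0
nadph	C0
q	C0
qh2	C0
hpp	C0H1
pdo_ext	C3H8O2
pdo12_ext	C3H8O2
hp3_ext	C3H6O3
pa_ext	C3H6O2
but_ext	C4H8O2
adp6_ext	C6H10O4
lys_ext	C6H14N2O2
dap_ext	C5H14N2
iprn_ext	C5H8
bdo23_ext	C4H10O2
bdo14_ext	C4H10O2
gaba_ext	C4H9NO2
mal_ext	C4H6O5
asp_ext	C4H7NO4
poh_ext	C3H8O
paba_ext	C7H7NO2
phba_ext	C7H6O3
btoh_ext	C4H10O
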