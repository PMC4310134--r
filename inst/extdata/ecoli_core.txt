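# Anaerobic E. coli core carbon network, transcribed for elementary mode
# screening of electro-fermentation.  57 species, 75 reactions (24 reversible).
#
# Conventions: ids ending in "_ext" are external (exchangeable, excluded from
# the steady-state matrix).  hpp is the periplasmic proton pool that carries
# the proton motive force; water, cytosolic protons and free phosphate are
# not balanced.  CO2/bicarbonate is lumped into one species.  Cofactor pairs
# (ATP/ADP, NAD(P)/NAD(P)H, Q/QH2) carry no carbon.
#
# R1 is the biomass equation: precursor drains in mmol per gram dry weight
# (standard E. coli demand table, coefficients expressed in eighths to keep
# the exact arithmetic small), 40 C-mmol per biomass unit; ATP demand
# includes growth-associated maintenance and is calibrated against the
# anaerobic glucose biomass yield.

# --- biomass ---
R1: 0.25 g6p + 0.125 f6p + 0.875 r5p + 0.375 e4p + 0.125 gap + 1.5 pg3 + 0.5 pep + 2.875 pyr + 3.75 accoa + 1.75 oaa + 1.125 akg + 18.25 nadph + 3.5 nad + 58.75 atp -> biomass_ext + 3.25 co2 + 18.25 nadp + 3.5 nadh + 58.75 adp | irrev | biomass

# --- glucose uptake and Embden-Meyerhof-Parnas glycolysis ---
R2: glc_ext + pep -> g6p + pyr | irrev | core          # PTS glucose uptake
R3: g6p -> f6p | rev | core                            # phosphoglucose isomerase
R4: f6p + atp -> fbp + adp | irrev | core              # phosphofructokinase
R5: fbp -> dhap + gap | rev | core                     # FBP aldolase
R6: dhap -> gap | rev | core                           # triose phosphate isomerase
R7: gap + nad -> bpg + nadh | rev | core               # GAP dehydrogenase
R8: bpg + adp -> pg3 + atp | rev | core                # phosphoglycerate kinase
R9: pg3 -> pg2 | rev | core                            # phosphoglycerate mutase
R10: pg2 -> pep | rev | core                           # enolase
R11: pep + adp -> pyr + atp | irrev | core             # pyruvate kinase
R12: pyr + 2 atp -> pep + 2 adp | irrev | core         # PEP synthase
R13: fbp -> f6p | irrev | core                         # FBPase

# --- pentose phosphate and Entner-Doudoroff pathways ---
R14: g6p + nadp -> p6g + nadph | irrev | core          # G6P dehydrogenase + lactonase
R15: p6g + nadp -> ru5p + co2 + nadph | irrev | core   # 6PG dehydrogenase
R16: p6g -> pyr + gap | irrev | core                   # Entner-Doudoroff route (dehydratase + aldolase)
R17: dhap + 2 nadh -> pdo12_ext + 2 nad | irrev | core # methylglyoxal route to 1,2-propanediol (native redox sink)
R18: ru5p -> x5p | rev | core                          # Ru5P epimerase
R19: ru5p -> r5p | rev | core                          # Ru5P isomerase
R20: x5p + r5p -> s7p + gap | rev | core               # transketolase I
R21: s7p + gap -> e4p + f6p | rev | core               # transaldolase
R22: x5p + e4p -> f6p + gap | rev | core               # transketolase II

# --- pyruvate to acetyl-CoA ---
R23: pyr + nad -> accoa + co2 + nadh | irrev | core    # pyruvate dehydrogenase
R24: pyr -> accoa + form | irrev | core                # pyruvate formate lyase
R25: pyr + q -> ac + co2 + qh2 | irrev | core          # pyruvate oxidase

# --- tricarboxylic acid cycle, glyoxylate shunt, anaplerosis ---
R26: accoa + oaa -> cit | irrev | core                 # citrate synthase
R27: cit -> icit | rev | core                          # aconitase
R28: icit + nadp -> akg + co2 + nadph | rev | core     # isocitrate dehydrogenase
R29: akg + nad -> succoa + co2 + nadh | irrev | core   # 2-oxoglutarate dehydrogenase
R30: succoa + adp -> succ + atp | rev | core           # succinyl-CoA synthetase
R31: succ + q -> fum + qh2 | irrev | core              # succinate dehydrogenase
R32: fum + qh2 -> succ + q | irrev | core              # fumarate reductase
R33: fum -> mal | rev | core                           # fumarase
R34: mal + nad -> oaa + nadh | rev | core              # malate dehydrogenase
R35: mal + q -> oaa + qh2 | irrev | core               # malate:quinone oxidoreductase
R36: icit + accoa -> succ + mal | irrev | core         # glyoxylate shunt (ICL + malate synthase)
R37: dhap -> lac | irrev | core                        # methylglyoxal bypass (lumped)
R38: pep + co2 -> oaa | irrev | core                   # PEP carboxylase
R39: oaa + atp -> pep + co2 + adp | irrev | core       # PEP carboxykinase
R40: mal + nad -> pyr + co2 + nadh | irrev | core      # malic enzyme (NAD)
R41: mal + nadp -> pyr + co2 + nadph | irrev | core    # malic enzyme (NADP)
R42: cit -> oaa + ac | irrev | core                    # citrate lyase

# --- glycerol degradation ---
R43: glyc + atp -> g3p + adp | irrev | core            # glycerol kinase
R44: g3p + nad -> dhap + nadh | rev | core             # glycerol-3-P dehydrogenase (NAD)
R45: g3p + q -> dhap + qh2 | irrev | core              # glycerol-3-P dehydrogenase (quinone)
R46: dhap + nadph -> g3p + nadp | irrev | core         # glycerol-3-P dehydrogenase (NADPH)

# --- transhydrogenases ---
R47: nadh + nadp + 0.33 atp -> nad + nadph + 0.33 adp | irrev | core  # membrane transhydrogenase
R48: nadph + nad -> nadp + nadh | irrev | core         # soluble transhydrogenase

# --- electron transport chain and energy conservation ---
R49: nadh + q -> nad + qh2 + 4 hpp | irrev | core      # NADH dehydrogenase I (pumping)
R50: nadh + q -> nad + qh2 | irrev | core              # NADH dehydrogenase II
R51: adp + 3 hpp -> atp | rev | core                   # ATP synthase
R52: hpp -> | irrev | core                             # proton leak

# --- anaerobic fermentation branches ---
R53: pyr + nadh -> lac + nad | rev | core              # lactate dehydrogenase
R54: lac + q -> pyr + qh2 | irrev | core               # lactate:quinone oxidoreductase
R55: accoa -> actp | rev | core                        # phosphotransacetylase
R56: actp + adp -> ac + atp | rev | core               # acetate kinase
R57: ac + 2 atp -> accoa + 2 adp | irrev | core        # acetyl-CoA synthetase
R58: accoa + nadh -> acald + nad | rev | core          # acetaldehyde dehydrogenase
R59: acald + nadh -> etoh + nad | rev | core           # alcohol dehydrogenase
R60: acald + nadp -> ac + nadph | irrev | core         # aldehyde dehydrogenase (NADP)
R61: form -> co2 + h2 | irrev | core                   # formate hydrogen lyase
R62: h2 + q -> qh2 | irrev | core                      # hydrogenase
R63: form + q -> co2 + qh2 | irrev | core              # formate dehydrogenase

# --- import and export ---
R64: glyc_ext -> glyc | irrev | exchange               # glycerol uptake
R65: glyc -> glyc_ext | irrev | exchange               # glycerol secretion
R66: fum_ext -> fum | irrev | exchange                 # fumarate uptake
R67: fum -> fum_ext | irrev | exchange                 # fumarate secretion
R68: co2 -> co2_ext | irrev | exchange                 # CO2 evolution
R69: ac -> ac_ext | irrev | exchange                   # acetate secretion
R70: etoh -> etoh_ext | irrev | exchange               # ethanol secretion
R71: lac -> lac_ext | irrev | exchange                 # lactate secretion
R72: form -> form_ext | irrev | exchange               # formate secretion
R73: succ -> succ_ext | irrev | exchange               # succinate secretion
R74: h2 -> h2_ext | irrev | exchange                   # hydrogen evolution
R75: pyr -> pyr_ext | irrev | exchange                 # pyruvate secretion
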