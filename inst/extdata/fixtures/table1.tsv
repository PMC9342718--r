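# Baseline/endline coverage (percent) and lives saved per channel, 2008-2014 Ghana
# evaluation, both analysis modes. Transcribed exactly as printed. NA = channel
# disabled in that mode (intervention-based modelling excludes direct stunting/
# wasting entry; direct-entry modelling excludes the complementary-feeding
# pathway and SAM's wasting route shows 0). printed_change is the table's own
# "Coverage change" column, which for some rows differs from endline - baseline
# as printed (e.g. DPT 10.8 vs 10.0); it is preserved verbatim.
# The intervention-mode ITN/IRS value was printed 6433 (no thousands separator).
intervention	period	baseline_coverage	endline_coverage	printed_change	lives_saved_intervention	share_intervention	lives_saved_direct	share_direct
Tetanus toxoid vaccination (TT)	pregnancy	86.0	88.0	2.0	95	0.3	95	0.2
Prevention of malaria in pregnancy	pregnancy	43.7	67.5	23.8	810	2.3	777	1.6
Syphilis detection and treatment	pregnancy	23.6	24.0	0.4	4	0.0	4	0.0
Prevention of mother-to-child transmission of HIV (including breastfeeding choices) (PMTCT)	pregnancy	0.0	23.3	23.3	1445	4.2	1446	3.0
Maternal age and birth order	pregnancy	NA	NA	NA	2	0.0	2	0.0
Clean birth environment	childbirth	46.8	59.9	13.1	736	2.1	736	1.5
Immediate drying and additional stimulation	childbirth	52.3	66.9	14.6	809	2.3	808	1.7
Thermal protection	childbirth	56.5	72.2	15.8	1205	3.5	1205	2.5
Clean cord care	childbirth	54.5	69.7	15.2	1318	3.8	1318	2.7
Antibiotics for preterm or prolonged premature rupture of the membranes (PROM)	childbirth	42.7	54.7	11.9	320	0.9	320	0.7
Parenteral administration of antibiotics	childbirth	42.7	54.7	11.9	320	0.9	320	0.7
Assisted vaginal delivery	childbirth	14.4	18.5	4.0	439	1.3	439	0.9
Neonatal resuscitation	childbirth	31.4	40.2	8.8	988	2.9	988	2.1
Caesarean delivery	childbirth	48.3	76.4	28.1	4145	12.0	4145	8.6
Age-appropriate breastfeeding practices	breastfeeding	60.6	50.0	-10.6	-1711	-5.0	-1786	-3.7
Change in stunting prevalence	preventive	27.5	18.8	8.7	NA	NA	4315	9.0
Vitamin A supplementation (2 doses)	preventive	24.0	23.0	-1.0	-21	-0.1	-21	0.0
Basic sanitation	preventive	12.7	16.5	3.8	120	0.3	115	0.2
Point-of-use filtered water	preventive	0.9	0.8	-0.1	-7	0.0	-7	0.0
Piped water	preventive	39.4	35.3	-4.2	-191	-0.6	-190	-0.4
Handwashing with soap	preventive	0.0	40.9	40.9	249	0.7	234	0.5
Insecticide-treated net/indoor residual spraying (ITN/IRS)	preventive	41.7	70.9	29.2	6433	18.7	6437	13.4
Complementary feeding (via reduction in stunting)	preventive	42.5	24.4	-18.1	394	1.1	NA	NA
Complementary feeding (via reduction in wasting)	preventive	42.5	24.4	-18.0	428	1.2	NA	NA
Diphtheria, pertussis, and tetanus (DPT) vaccine	vaccine	88.0	98.0	10.8	869	2.5	870	1.8
Haemophilus influenzae type B	vaccine	88.0	98.0	10.8	244	0.7	243	0.5
Pneumococcal vaccine (3 doses)	vaccine	0.0	99.0	99.0	3931	11.4	3938	8.2
Rotavirus vaccine (3 doses)	vaccine	0.0	98.0	98.0	655	1.9	669	1.4
Measles vaccine (1 dose)	vaccine	89.8	92.0	5.4	239	0.7	226	0.5
Case management of neonatal sepsis/pneumonia	curative	57.1	73.1	16.0	4271	12.4	4271	8.9
Oral rehydration salts (ORS)	curative	44.5	48.6	4.1	985	2.9	917	1.9
Antibiotics for treatment of dysentery	curative	46.4	42.2	-4.0	-116	-0.3	-118	-0.2
Zinc for treatment of diarrhoea	curative	1.8	7.4	5.6	223	0.6	208	0.4
Oral antibiotics for pneumonia	curative	50.7	52.6	1.9	422	1.2	396	0.8
Vitamin A for treatment of measles	curative	24.0	23.0	-1.0	-9	0.0	-9	0.0
Artemisinin-based combination therapy (ACTs) (within 48hours)	curative	11.3	26.2	14.9	4322	12.5	4325	9.0
Treatment for severe acute malnutrition (SAM)	curative	0.0	2.7	2.7	37	0.1	0	0.0
Change in wasting prevalence	curative	8.6	4.7	3.9	NA	NA	10372	21.6
Cotrimoxazole	curative	2.7	4.1	1.4	31	0.1	31	0.1
ART for children	curative	7.4	22.7	15.2	43	0.1	45	0.1
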