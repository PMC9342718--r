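# Universal scale-up: lives saved in 2014 when every intervention's 2014
# coverage is raised to 100%, with the printed coverage-increase column
# (target minus baseline coverage; for most rows 100 - the 2008 value, the
# breastfeeding row instead prints 100 - the 2014 value). Transcribed as
# printed; the maternal-age row has no coverage increase.
intervention	period	coverage_increase	lives_saved	share
Tetanus toxoid vaccination (TT)	pregnancy	14.0	669	0.6
Prevention of malaria in pregnancy	pregnancy	56.3	1896	1.7
Syphilis detection and treatment	pregnancy	1.1	15	0.0
Prevention of mother-to-child transmission of HIV (including breastfeeding choices) (PMTCT)	pregnancy	100.0	1450	1.3
Maternal age and birth order	pregnancy	NA	2	0.0
Clean birth environment	childbirth	35.2	1850	1.7
Immediate drying and additional stimulation	childbirth	39.3	2078	1.9
Thermal protection	childbirth	42.4	3026	2.8
Clean cord care	childbirth	40.9	3041	2.8
Antibiotics for preterm or prolonged premature rupture of the membranes (PROM)	childbirth	32.1	836	0.8
Parenteral administration of antibiotics	childbirth	32.1	836	0.8
Assisted vaginal delivery	childbirth	10.8	1104	1.0
Neonatal resuscitation	childbirth	23.6	2511	2.3
Parenteral administration of uterotonics	childbirth	38.3	0	0.0
Cesarean delivery	childbirth	51.7	7134	6.6
Age-appropriate breastfeeding practices	breastfeeding	50.0	7935	7.3
Vitamin A supplementation	preventive	76.0	1247	1.2
Basic sanitation	preventive	87.3	1992	1.8
Point-of-use filtered water	preventive	99.1	5560	5.1
Piped water	preventive	60.6	2140	2.0
Handwashing with soap	preventive	100.0	387	0.4
Hygienic disposal of children's stools	preventive	57.6	0	0.0
Households protected from malaria (ITN/IRS)	preventive	58.3	12906	11.9
Complementary feeding (via reduction in stunting)	preventive	57.5	1361	1.3
Complementary feeding (via reduction in wasting)	preventive	57.5	464	0.4
DPT vaccine	vaccine	12.0	882	0.8
Haemophilus influenzae b vaccine	vaccine	12.0	222	0.2
Pneumococcal vaccine (3 doses)	vaccine	100.0	3433	3.2
Rotavirus vaccine (3 doses)	vaccine	100.0	416	0.4
Measles vaccine (1 dose)	vaccine	10.2	970	0.9
Case management of neonatal sepsis/pneumonia	curative	16.0	3617	3.3
Oral rehydration solution (ORS)	curative	55.5	4911	4.5
Antibiotics for treatment of dysentery	curative	53.6	540	0.5
Zinc for the treatment of diarrhea	curative	98.2	1438	1.3
Oral antibiotics for pneumonia	curative	49.3	9173	8.5
Vitamin A for treatment of measles	curative	76.0	237	0.2
Artemisinin compounds for the treatment of malaria (ACT)	curative	88.7	21204	19.6
Treatment for severe acute malnutrition (SAM)	curative	100.0	830	0.8
Cotrimoxazole	curative	97.3	31	0.0
Antiretroviral therapy (ART)	curative	92.6	46	0.0
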