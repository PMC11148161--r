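# Reduced exposure models and interaction terms for the five CYP
# perpetrators. The source model drove its DDI simulations with full PBPK
# perpetrator models whose parameter tables are not reproduced here; every
# entry below is a literature-sourced substitute (flagged per record), and
# the victim-side AUC/Cmax ratios must be read with that substitution in
# mind. PK: one-compartment first-order oral (cl_f L/h, v_f L, ka 1/h,
# fu fraction). Interaction: unbound competitive Ki (uM) and/or Emax/EC50u
# induction per enzyme; induced enzymes relax with a 36 h turnover
# half-life.
itraconazole:
  provenance: literature substitute (fu_eff includes the equipotent
    hydroxy-metabolite's contribution)
  molecular_weight: 705.6
  regimen: {dose_mg: 200, interval: 12}
  pk: {cl_f: 19.4, v_f: 700, ka: 0.5, fu: 0.036}
  inhibition: {CYP3A4: 0.0013}
fluconazole:
  provenance: literature substitute
  molecular_weight: 306.3
  regimen: {dose_mg: 150, interval: 24}
  pk: {cl_f: 1.2, v_f: 50, ka: 1.0, fu: 0.89}
  inhibition: {CYP3A4: 10.7, CYP2C9: 15.0}
fluvoxamine:
  provenance: literature substitute
  molecular_weight: 318.3
  regimen: {dose_mg: 50, interval: 24}
  pk: {cl_f: 75.8, v_f: 1750, ka: 1.0, fu: 0.23}
  inhibition: {CYP1A2: 0.01, CYP3A4: 0.2, CYP2C9: 6.0}
rifampicin:
  provenance: literature substitute
  molecular_weight: 822.9
  regimen: {dose_mg: 600, interval: 24}
  pk: {cl_f: 10.0, v_f: 55, ka: 1.0, fu: 0.20}
  inhibition: {CYP3A4: 18.5}
  induction:
    CYP3A4: {emax: 9.0, ec50_u: 0.10}
    CYP2C9: {emax: 2.0, ec50_u: 0.10}
    CYP1A2: {emax: 0.7, ec50_u: 0.10}
efavirenz:
  provenance: literature substitute
  molecular_weight: 315.7
  regimen: {dose_mg: 600, interval: 24}
  pk: {cl_f: 9.0, v_f: 250, ka: 0.6, fu: 0.01}
  inhibition: {CYP2C9: 20.0}
  induction:
    CYP3A4: {emax: 2.5, ec50_u: 0.02}
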