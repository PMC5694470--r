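# Example schema: maps the columns of a lab-style assay table onto the
# internal panel fields and declares concentration units.
name: Drug
eftpc: EFTPC_uM
channels:
  IKr:  {ic50: hERG_IC50_uM, hill: hERG_hill}
  ICaV: {ic50: CaV_IC50_uM}
  INaL: {ic50: NaL_IC50_nM}
units:
  eftpc: uM
  IKr: uM
  ICaV: uM
  INaL: nM
labels:
  crediblemeds: CM_category
  label_warning: TdP_label_warning
trapping: trapping_ratio
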