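# Phenotype gate panel for pancreatic lesion immune profiling.
# Ordered boolean gates over marker positivity; more specific gates
# (more constrained markers) take precedence automatically.
- name: Treg
  positive: [CD3, CD4, FOXP3]
  negative: [PD1]
- name: T_CD4_exhausted
  positive: [CD3, CD4, CD45RO, TOX2, PD1]
- name: T_CD4_central_memory
  positive: [CD3, CD4, CD45RO, CCR7, HLADR]
- name: T_CD4_senescent
  positive: [CD3, CD4, CD45RO, CD57]
- name: T_CD8_cytotoxic
  positive: [CD3, CD8, GZMB]
- name: T_CD8_memory
  positive: [CD3, CD8, CD45RO]
- name: B_germinal_center
  positive: [CD20, CD21, CD23]
- name: B_proliferating
  positive: [CD20, CD45RA, KI67]
- name: T_CD4
  positive: [CD3, CD4]
- name: T_CD8
  positive: [CD3, CD8]
- name: B_cell
  positive: [CD20]
- name: T_cell
  positive: [CD3]
- name: macrophage
  positive: [CD68]
- name: dendritic_cell
  positive: [DCSIGN]
- name: NK_cell
  positive: [CD57]
  negative: [CD3]
- name: fibroblast
  positive: [COL, SMA, VIM]
- name: endothelial_HEV
  positive: [PDPN]
- name: epithelial
  positive: [CK]
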