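# Representative antidiabetic formulary mapped to Multum-style therapeutic
# categories. Editable: extend `categories` (drug: category) and, for any drug
# categorized as "combinations", list its ingredients under `combinations`.
categories:
  metformin: biguanides
  glipizide: SUs
  glyburide: SUs
  glimepiride: SUs
  chlorpropamide: SUs
  tolazamide: SUs
  tolbutamide: SUs
  repaglinide: meglitinides
  nateglinide: meglitinides
  pioglitazone: TZDs
  rosiglitazone: TZDs
  troglitazone: TZDs
  acarbose: AGIs
  miglitol: AGIs
  sitagliptin: DPP-4is
  saxagliptin: DPP-4is
  linagliptin: DPP-4is
  alogliptin: DPP-4is
  canagliflozin: SGLT2is
  dapagliflozin: SGLT2is
  empagliflozin: SGLT2is
  ertugliflozin: SGLT2is
  exenatide: GLP-1RAs
  liraglutide: GLP-1RAs
  dulaglutide: GLP-1RAs
  semaglutide: GLP-1RAs
  albiglutide: GLP-1RAs
  lixisenatide: GLP-1RAs
  insulin glargine: insulin
  insulin detemir: insulin
  insulin aspart: insulin
  insulin lispro: insulin
  insulin degludec: insulin
  insulin isophane: insulin
  insulin regular: insulin
  insulin glulisine: insulin
  metformin/sitagliptin: combinations
  metformin/saxagliptin: combinations
  glipizide/metformin: combinations
  glyburide/metformin: combinations
  pioglitazone/metformin: combinations
  pioglitazone/glimepiride: combinations
  rosiglitazone/metformin: combinations
  alogliptin/metformin: combinations
  canagliflozin/metformin: combinations
  dapagliflozin/metformin: combinations
  empagliflozin/linagliptin: combinations
  insulin degludec/liraglutide: combinations
combinations:
  metformin/sitagliptin: [metformin, sitagliptin]
  metformin/saxagliptin: [metformin, saxagliptin]
  glipizide/metformin: [glipizide, metformin]
  glyburide/metformin: [glyburide, metformin]
  pioglitazone/metformin: [pioglitazone, metformin]
  pioglitazone/glimepiride: [pioglitazone, glimepiride]
  rosiglitazone/metformin: [rosiglitazone, metformin]
  alogliptin/metformin: [alogliptin, metformin]
  canagliflozin/metformin: [canagliflozin, metformin]
  dapagliflozin/metformin: [dapagliflozin, metformin]
  empagliflozin/linagliptin: [empagliflozin, linagliptin]
  insulin degludec/liraglutide: [insulin degludec, liraglutide]
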