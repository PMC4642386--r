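# silence R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  ".", "day", "period", "covered", "len", "pdc_sub", "adherent", "pdc",
  "covered_days", "n_subclasses", "patient_id", "drug_class", "subclass",
  "days_supply", "fill_date"
))

#' @importFrom data.table := .N
NULL
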