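# data.table non-standard evaluation symbols used in evaluate_cohort()
utils::globalVariables(c("pid", "day", "msk", "spec", ".", "patient_id"))

#' @importFrom data.table := .N .SD data.table
NULL
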