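#' @importFrom stats setNames
#' @importFrom utils head
NULL

.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".N", "count_C", "count_T", "is_c", "promoter", "C_stage", "T_stage",
  "C_normal", "T_normal", "level_stage", "level_normal", "gene", "stage",
  "true_status", "status", "n", "key", "e"
))
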