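# data.table is used via := and NSE column names throughout
#' @import data.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "adherent", "block", "contrast", "date", "day_index", "heart_rate",
  "heart_rate_present", "label", "minute", "n_missing", "participant_id",
  "resolved_steps", "steps", "temperature_f", "total", "total_steps",
  "value", "wear", "wear_fraction", "weekday", "weight", "imputed"))
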