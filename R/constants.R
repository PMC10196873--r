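# closed vocabularies shared across modules
.nvhap_vocab <- list(
  bed_size_class = c("1-99", "100-199", "200-299", ">=300"),
  region         = c("Midwest", "Northeast", "South", "West"),
  sex            = c("female", "male"),
  race           = c("Asian", "Black", "White", "Other"),
  disposition    = c("home", "rehabilitation", "skilled_nursing", "hospice",
                     "death", "other"),
  service        = c("cardiology", "medicine", "surgery", "neuroscience",
                     "oncology", "other")
)

.comorbidity_flags <- c("congestive_heart_failure", "chronic_lung_disease",
                        "diabetes", "chronic_liver_disease", "cancer",
                        "neurological_disease", "chronic_kidney_disease")

# round-half-up used for display percentages (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_cls <- function(cls, msg, ...) {
  stop(structure(class = c(cls, "nvhap_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
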