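# Structured conditions so callers (and the CLI) can distinguish bad input
# from violated invariants from misuse of the API.

pcv_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "plastocov_error")))
}

#' @noRd
input_error <- function(msg) pcv_stop(msg, "plastocov_input_error")

#' @noRd
validation_error <- function(msg) pcv_stop(msg, "plastocov_validation_error")

#' @noRd
contract_error <- function(msg) pcv_stop(msg, "plastocov_contract_error")

#' @noRd
usage_error <- function(msg) pcv_stop(msg, "plastocov_usage_error")

# Warnings carry a subclass so tests and the QC log can filter them.
pcv_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "plastocov_warning")))
}

# Informational notices (e.g. "no IR annotations found") are messages,
# never warnings: they do not indicate a QC problem.
pcv_inform <- function(msg) {
  message(msg)
}

#' Reverse complement of a nucleotide string
#' @param x single character string over the DNA alphabet.
#' @return the reverse complement, as an uppercase character string.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# One structured warning record; comparisons return these in a data.frame
# alongside emitting them as R conditions.
warning_record <- function(class, message) {
  data.frame(class = class, message = message, stringsAsFactors = FALSE)
}

empty_warnings <- function() {
  data.frame(class = character(), message = character(), stringsAsFactors = FALSE)
}
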