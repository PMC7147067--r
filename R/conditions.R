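# Classed conditions. All package errors inherit from "epimax_error"; the
# subclass determines the CLI exit code (see run_find).

.stop_cls <- function(class, fmt, ...) {
  msg <- if (length(list(...)) > 0L) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c(class, "epimax_error")))
}

.stop_parse      <- function(fmt, ...) .stop_cls("epimax_parse_error", fmt, ...)
.stop_structure  <- function(fmt, ...)
  .stop_cls(c("epimax_structure_error", "epimax_parse_error"), fmt, ...)
.stop_expression <- function(fmt, ...)
  .stop_cls(c("epimax_expression_error", "epimax_parse_error"), fmt, ...)
.stop_model      <- function(fmt, ...)
  .stop_cls(c("epimax_model_error", "epimax_parse_error"), fmt, ...)
.stop_domain     <- function(fmt, ...)
  .stop_cls(c("epimax_domain_error", "epimax_parse_error"), fmt, ...)
.stop_validation <- function(fmt, ...)
  .stop_cls("epimax_validation_error", fmt, ...)
.stop_nosolution <- function(fmt, ...)
  .stop_cls("epimax_nosolution_error", fmt, ...)
.stop_infeasible <- function(fmt, ...)
  .stop_cls(c("epimax_infeasible_error", "epimax_nosolution_error"), fmt, ...)
.stop_io         <- function(fmt, ...) .stop_cls("epimax_io_error", fmt, ...)
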