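`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derivation from one global seed, so adding a
# stage never perturbs another stage's random stream. Kept < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("mrmediate_config_error", "error")))
}

stop_no_instruments <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("mrmediate_no_instruments_error", "error")))
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
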