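`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed for a named random substream. Keeps every derived
# seed in [0, 2^31 - 2] so set.seed() always accepts it.
substream_seed <- function(seed, name) {
  h <- 0
  for (cp in utf8ToInt(as.character(name))) h <- (h * 131 + cp) %% 2147483629
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Classed conditions so callers can distinguish schema problems from
# referential problems from plain I/O failures.
qsip_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "qsip_error")))
}

stopifnot_cols <- function(df, cols, table) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    qsip_error("qsip_schema_error",
               sprintf("table '%s' is missing column(s): %s",
                       table, paste(miss, collapse = ", ")),
               table = table, columns = miss)
  invisible(df)
}
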