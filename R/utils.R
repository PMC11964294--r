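# Internal helpers: argument checks, seed substreams, counters.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("heatomics_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("heatomics_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(p, what = "p") {
  bad <- !is.na(p) & (p < 0 | p > 1 | !is.finite(p))
  if (any(bad))
    stop_validation(what, " values outside [0, 1]: ",
                    paste(utils::head(which(bad), 5L), collapse = ", "))
  invisible(p)
}

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_input(what, " must be TRUE or FALSE")
  invisible(x)
}

check_number <- function(x, what, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (length(x) != 1L || (!allow_na && is.na(x)) || !is.numeric(x))
    stop_input(what, " must be a single number")
  if (!is.na(x) && (x < lower || x > upper))
    stop_input(what, " must be in [", lower, ", ", upper, "], got ", x)
  invisible(x)
}

# Deterministic substream seed derived from a 32-bit master seed.  Every
# generator takes the master seed plus a stream index so multi-stage
# fixtures are reproducible stage by stage.
derive_seed <- function(seed, stream) {
  seed <- as.integer(seed)
  ((abs(seed) %% 1000003L) * 2017L + as.integer(stream) * 7919L + 13L) %%
    2147483587L
}

new_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$counts <- integer(0)
  env
}

count_event <- function(counter, name, by = 1L) {
  cur <- counter$counts[name]
  counter$counts[name] <- if (is.na(cur)) by else cur + by
  invisible(counter)
}

counter_as_list <- function(counter) as.list(counter$counts)
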