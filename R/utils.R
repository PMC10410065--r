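# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a fixed RNG state, restoring the caller's state after
#'
#' All generators in the package are pure functions of (config, seed): they
#' seed the RNG locally and leave the global RNG stream untouched.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed; kept < 2^31 so it is a valid R integer.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347L) %% 2147483629)
}

stop_config <- function(...) {
  stop(structure(
    class = c("pleionet_config_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

stop_input <- function(...) {
  stop(structure(
    class = c("pleionet_input_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_input(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

# canonical unordered pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", check.names = FALSE)
}
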