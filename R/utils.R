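#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers never perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# Derived seeds stay below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) + as.numeric(offset)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Internal logging at INFO level to stderr (and optionally a file)
#' @noRd
cobel_log <- function(..., file = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  invisible(msg)
}

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Encode a DNA string as integer codes 1..4 (A,C,G,T), NA for anything else.
encode_dna <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
}

decode_dna <- function(codes) paste(DNA_BASES[codes], collapse = "")

revcomp_string <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  out <- rev(unname(COMPLEMENT[chars]))
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}
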