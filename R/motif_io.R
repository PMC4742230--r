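#' Read a motif library
#'
#' Supports MEME minimal format (the `letter-probability matrix` blocks)
#' and a long-format TSV with header columns
#' `id, tf, position, A, C, G, T`, one row per motif position. Dimer
#' motifs (factor names containing `::`) are kept as ordinary concatenated
#' PWMs.
#'
#' @param path path to the motif file.
#' @param format `"auto"` (default; MEME if the file starts with
#'   `MEME version`), `"meme"` or `"tsv"`.
#' @param pseudocount passed to [pwm()].
#' @return a named list of [pwm] objects.
#' @export
read_motifs <- function(path, format = c("auto", "meme", "tsv"),
                        pseudocount = 1e-3) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^MEME version", first)) "meme" else "tsv"
  }
  if (format == "meme") read_motifs_meme(path, pseudocount)
  else read_motifs_tsv(path, pseudocount)
}

read_motifs_meme <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) stop("no MOTIF blocks found in ", path)
  out <- list()
  for (m in motif_at) {
    toks <- strsplit(trimws(lines[m]), "\\s+")[[1]]
    id <- toks[2]
    tf <- if (length(toks) >= 3) toks[3] else id
    hdr_rel <- grep("^letter-probability matrix", lines[seq(m + 1, length(lines))])
    if (!length(hdr_rel)) stop("motif ", id, " has no letter-probability matrix")
    hdr <- m + hdr_rel[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[seq(hdr + 1, hdr + w)]
    mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(x) as.numeric(x[1:4]), numeric(4)))
    kind <- if (grepl("::", tf, fixed = TRUE)) "dimer" else "monomer"
    out[[id]] <- pwm(t(mat), id = id, tf_name = tf, kind = kind,
                     pseudocount = pseudocount)
  }
  out
}

read_motifs_tsv <- function(path, pseudocount = 1e-3) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "tf", "position", "A", "C", "G", "T")
  if (!all(need %in% names(df))) {
    stop("motif TSV needs columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (id in unique(df$id)) {
    sub <- df[df$id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    mat <- t(as.matrix(sub[, c("A", "C", "G", "T")]))
    kind <- if (grepl("::", sub$tf[1], fixed = TRUE)) "dimer" else "monomer"
    out[[id]] <- pwm(mat, id = id, tf_name = sub$tf[1], kind = kind,
                     pseudocount = pseudocount)
  }
  out
}

#' Write a motif library as TSV
#'
#' Long format with header `id, tf, position, A, C, G, T`; the inverse of
#' [read_motifs()] with `format = "tsv"` (up to pseudocount
#' regularisation, which is idempotent at `pseudocount = 0`).
#'
#' @param pwms a list of [pwm] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motifs_tsv <- function(pwms, path) {
  rows <- lapply(pwms, function(p) {
    data.frame(id = p$id, tf = p$tf_name,
               position = seq_len(pwm_length(p)),
               A = p$freqs["A", ], C = p$freqs["C", ],
               G = p$freqs["G", ], T = p$freqs["T", ],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
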