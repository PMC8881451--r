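#' Parse a G-rich oligonucleotide sequence into runs and loops
#'
#' Accepts either expanded strings (`"GGAGGGGAGG"`), run notation with a
#' letter followed by a repeat count (`"G2AG4AG2"`), or bracketed
#' non-nucleotide tokens for the propyl (C3) linker and the abasic residue
#' (`"GG[li]GGGG[li]GG"`). The layout reports maximal G-runs as 0-based
#' half-open spans and every non-G position as a loop residue; the family
#' G2XG4XG2 studied here carries its loops at 0-based indices 2 and 7
#' (1-based positions 3 and 8, the labels used in reports).
#'
#' @param seq sequence string over the alphabet G, A, T, C plus bracketed
#'   `[li]` / `[ab]` tokens; digits repeat the preceding token.
#' @return An object of class `oligo_layout` with elements `residues`
#'   (character vector of tokens), `g_runs` (data.frame of 0-based
#'   half-open `start`/`end`), and `loops` (data.frame with 0-based `index`,
#'   1-based `position`, and `residue`).
#' @examples
#' parse_sequence("G2AG4AG2")
#' parse_sequence("GG[ab]GGGG[ab]GG")
#' @export
parse_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("`seq` must be a single non-empty string")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  residues <- character(0)
  i <- 1L
  repeat_token <- function(tok, i) {
    # consume optional digits following a token; returns c(count, next index)
    j <- i
    while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
    count <- if (j > i) as.integer(paste(chars[i:(j - 1L)], collapse = "")) else 1L
    if (count < 1L) stop(sprintf("repeat count 0 at position %d", i))
    list(count = count, nxt = j)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > i)
      if (!length(close)) stop(sprintf("unterminated '[' at position %d", i))
      close <- close[1L]
      tok <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (!tok %in% c("li", "ab")) {
        stop(sprintf("unknown token '[%s]' at position %d", tok, i))
      }
      rep_ <- repeat_token(tok, close + 1L)
      residues <- c(residues, rep(tok, rep_$count))
      i <- rep_$nxt
    } else if (ch %in% c("G", "A", "T", "C")) {
      rep_ <- repeat_token(ch, i + 1L)
      residues <- c(residues, rep(ch, rep_$count))
      i <- rep_$nxt
    } else {
      stop(sprintf("unknown token '%s' at position %d", ch, i))
    }
  }
  is_g <- residues == "G"
  # maximal G-runs as 0-based half-open [start, end)
  r <- rle(is_g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  g_runs <- data.frame(start = starts[r$values], end = ends[r$values])
  loop_idx <- which(!is_g) - 1L
  loops <- data.frame(index = loop_idx, position = loop_idx + 1L,
                      residue = residues[loop_idx + 1L],
                      stringsAsFactors = FALSE)
  structure(
    list(residues = residues, g_runs = g_runs, loops = loops),
    class = "oligo_layout"
  )
}

#' @export
print.oligo_layout <- function(x, ...) {
  cat("Oligonucleotide layout:", paste(x$residues, collapse = ""), "\n")
  cat(sprintf(" %d residues, %d G-run(s), %d loop residue(s)\n",
              length(x$residues), nrow(x$g_runs), nrow(x$loops)))
  if (nrow(x$loops)) {
    cat(" loops:",
        paste(sprintf("%s at position %d", x$loops$residue, x$loops$position),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
format.oligo_layout <- function(x, ...) paste(x$residues, collapse = "")
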