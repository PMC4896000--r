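#' Write or read a per-event feature table as tab-delimited text
#'
#' Tab-separated, header row, UTF-8, "." decimal separator - the plain
#' export format of the feature chain. Reading validates that the
#' metadata columns are present and that feature values are finite.
#'
#' @param table Feature table (data.frame).
#' @param path File path.
#' @param required_metadata Metadata columns that must be present on read.
#' @return `read_feature_table` returns an `experiment_table`.
#' @export
write_feature_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path,
                               required_metadata = c("treatment", "time_h",
                                                     "replicate")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required_metadata, names(df))
  if (length(miss))
    stop("missing metadata column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) {
    if (any(!is.finite(df[[cn]])))
      stop(sprintf("non-finite values in column '%s' (first at row %d)",
                   cn, which(!is.finite(df[[cn]]))[1]), call. = FALSE)
  }
  as_experiment_table(df, provenance = "file")
}

# ---- Minimal FCS 3.1 support -------------------------------------------
#
# Feature tables travel as FCS in the cytometry tool chain. No FCS
# library is available to this package, so a minimal, self-contained
# FCS 3.1 writer/reader is provided: single dataset, list-mode, 32-bit
# float, little endian, one parameter per numeric feature, with
# non-numeric metadata stored as custom keywords per event-index-encoded
# companion columns. Character metadata columns (treatment, labels) are
# stored as keyword-encoded level dictionaries plus an integer code
# parameter.

.fcs_delim <- "/"

.fcs_text_segment <- function(keywords) {
  esc <- function(x) gsub(.fcs_delim, paste0(.fcs_delim, .fcs_delim),
                          as.character(x), fixed = TRUE)
  paste0(.fcs_delim,
         paste0(vapply(names(keywords), esc, character(1)), .fcs_delim,
                vapply(unlist(keywords), esc, character(1)), .fcs_delim,
                collapse = ""))
}

#' Write or read a feature table as a minimal FCS 3.1 file
#'
#' Numeric columns become FCS parameters (32-bit float, list mode);
#' character columns are factor-encoded as integer parameters with their
#' level dictionaries stored as `SUBPOPDYN_LEVELS_<name>` keywords, so a
#' round trip restores them exactly.
#'
#' @param table Feature table.
#' @param path File path.
#' @return `read_fcs` returns a data.frame; parameter names come from the
#'   `$PnS` / `$PnN` keywords.
#' @export
write_fcs <- function(table, path) {
  df <- as.data.frame(table)
  is_chr <- vapply(df, is.character, logical(1))
  level_kw <- list()
  for (cn in names(df)[is_chr]) {
    f <- factor(df[[cn]])
    level_kw[[paste0("SUBPOPDYN_LEVELS_", cn)]] <-
      paste(levels(f), collapse = "\t")
    df[[cn]] <- as.integer(f)
  }
  mat <- as.matrix(as.data.frame(lapply(df, as.numeric)))
  n_par <- ncol(mat); n_evt <- nrow(mat)

  kw <- c(list(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_evt)),
    level_kw)
  for (p in seq_len(n_par)) {
    kw[[sprintf("$P%dN", p)]] <- colnames(mat)[p]
    kw[[sprintf("$P%dS", p)]] <- colnames(mat)[p]
    kw[[sprintf("$P%dB", p)]] <- "32"
    kw[[sprintf("$P%dE", p)]] <- "0,0"
    rng <- max(abs(mat[, p]), 1)
    kw[[sprintf("$P%dR", p)]] <- as.character(ceiling(rng) + 1)
  }

  header_len <- 58L
  data_len <- 4L * n_par * n_evt
  # Two-pass: offsets depend on the TEXT length, which contains offsets.
  fmt_off <- function(x) formatC(x, width = 8, flag = " ")
  build <- function(text_end, data_beg, data_end) {
    kw2 <- c(list("$BEGINDATA" = as.character(data_beg),
                  "$ENDDATA" = as.character(data_end)), kw)
    .fcs_text_segment(kw2)
  }
  text_beg <- header_len
  guess <- nchar(build(0, 0, 0), type = "bytes") + 40L
  repeat {
    text_end <- text_beg + guess - 1L
    data_beg <- text_end + 1L
    data_end <- data_beg + data_len - 1L
    text <- build(text_end, data_beg, data_end)
    pad <- guess - nchar(text, type = "bytes")
    if (pad >= 0) { text <- paste0(text, strrep(" ", pad)); break }
    guess <- nchar(text, type = "bytes") + 16L
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("FCS3.1    %s%s%s%s%s%s",
                    fmt_off(text_beg), fmt_off(text_end),
                    fmt_off(0), fmt_off(0), fmt_off(0), fmt_off(0)),
            con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

.fcs_parse_text <- function(raw_text) {
  s <- rawToChar(raw_text)
  delim <- substr(s, 1, 1)
  body <- substr(s, 2, nchar(s))
  # Escaped delimiters appear as doubled delimiters; split on single ones.
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # Rejoin empty parts produced by doubled delimiters.
  toks <- character(0); i <- 1
  while (i <= length(parts)) {
    tok <- parts[i]
    while (i < length(parts) && parts[i + 1] == "" &&
           i + 1 < length(parts)) {
      tok <- paste0(tok, delim, parts[i + 2])
      i <- i + 2
    }
    toks <- c(toks, tok)
    i <- i + 1
  }
  toks <- toks[!(toks == "" & seq_along(toks) == length(toks))]
  if (length(toks) %% 2 == 1) toks <- toks[-length(toks)]
  setNames(as.list(toks[seq(2, length(toks), 2)]),
           toks[seq(1, length(toks), 2)])
}

#' @rdname write_fcs
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.1")
    stop(sprintf("malformed FCS (bad magic at offset 0): %s", path),
         call. = FALSE)
  off <- function(a, b) as.integer(trimws(substr(header, a, b)))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  seek(con, text_beg)
  kw <- .fcs_parse_text(readBin(con, "raw", text_end - text_beg + 1L))
  n_par <- as.integer(kw[["$PAR"]]); n_evt <- as.integer(kw[["$TOT"]])
  if (!identical(kw[["$DATATYPE"]], "F"))
    stop("unsupported FCS datatype: ", kw[["$DATATYPE"]], call. = FALSE)
  data_beg <- as.integer(kw[["$BEGINDATA"]])
  seek(con, data_beg)
  vals <- readBin(con, "numeric", n = n_par * n_evt, size = 4L,
                  endian = "little")
  mat <- matrix(vals, nrow = n_evt, ncol = n_par, byrow = TRUE)
  cn <- vapply(seq_len(n_par), function(p) kw[[sprintf("$P%dN", p)]],
               character(1))
  colnames(mat) <- cn
  df <- as.data.frame(mat)
  for (nm in names(kw)) {
    if (startsWith(nm, "SUBPOPDYN_LEVELS_")) {
      col <- sub("SUBPOPDYN_LEVELS_", "", nm)
      if (col %in% names(df)) {
        levels <- strsplit(kw[[nm]], "\t", fixed = TRUE)[[1]]
        df[[col]] <- levels[as.integer(df[[col]])]
      }
    }
  }
  if ("replicate" %in% names(df))
    df$replicate <- as.integer(round(df$replicate))
  attr(df, "fcs_keywords") <- kw
  df
}
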