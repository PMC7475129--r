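#' Write a physiological trace to a delimited file
#'
#' Two tab-separated columns (time_s, value) preceded by a
#' \code{# sample_rate_hz:} header line (and optional subject/body-mass
#' metadata lines in the same comment format).
#'
#' @param trace a \code{flow_trace} or \code{pressure_trace}.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  fs <- trace$sample_rate_hz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %g", fs), con)
  if (!is.null(trace$subject_id))
    writeLines(sprintf("# subject_id: %s", trace$subject_id), con)
  if (!is.null(trace$body_mass_g))
    writeLines(sprintf("# body_mass_g: %g", trace$body_mass_g), con)
  t <- (seq_along(trace$samples) - 1) / fs
  utils::write.table(data.frame(time_s = t, value = trace$samples), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a physiological trace written by \code{\link{write_trace}}
#'
#' @param path input file.
#' @param class_ "flow_trace" or "pressure_trace".
#' @return the reconstructed trace object.
#' @export
read_trace <- function(path, class_ = "flow_trace") {
  lines <- readLines(path, n = 10)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^#\\s*", key, ":"), hdr)]
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  fs <- as.numeric(get("sample_rate_hz"))
  stop_if_not(is.finite(fs), "missing '# sample_rate_hz:' header")
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  obj <- list(samples = d$value, sample_rate_hz = fs,
              subject_id = get("subject_id"))
  bm <- get("body_mass_g")
  if (!is.null(bm)) obj$body_mass_g <- as.numeric(bm)
  structure(obj, class = class_)
}

#' Write a breath or event table as TSV
#'
#' @param x a data frame (\code{breath_table}, \code{resp_events}, ...).
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Read a breath table written by \code{\link{write_tsv}}
#'
#' @param path input file.
#' @param body_mass_g optional body mass attribute to attach.
#' @return a \code{breath_table}.
#' @export
read_breath_table <- function(path, body_mass_g = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(d, class = c("breath_table", "data.frame"),
            body_mass_g = body_mass_g)
}

#' Write a count table as feature-by-sample TSV
#'
#' First column \code{feature_id}, remaining columns one per sample.
#'
#' @param counts a \code{count_table}.
#' @param path output file.
#' @export
write_count_table <- function(counts, path) {
  d <- data.frame(feature_id = rownames(counts),
                  unclass(counts), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a feature-by-sample count table TSV
#'
#' @param path input file (first column feature IDs, header of sample IDs).
#' @param sample_data optional per-sample metadata data frame.
#' @return a \code{count_table}.
#' @export
read_count_table <- function(path, sample_data = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  count_table(m, sample_data)
}

#' Read module definitions
#'
#' Text format: a module starts with a line \code{MODULE_ID<TAB>name};
#' each following line is one pathway step listing its alternative KO
#' identifiers separated by commas; a blank line (or the next module header)
#' ends the module.
#'
#' @param path input file.
#' @return list of module definitions for \code{\link{aggregate_modules}}.
#' @export
read_module_definitions <- function(path) {
  lines <- readLines(path)
  defs <- list()
  cur <- NULL
  flush <- function(defs, cur) {
    if (!is.null(cur)) {
      stop_if_not(length(cur$steps) >= 1,
                  sprintf("module %s has no steps", cur$module_id))
      defs[[length(defs) + 1L]] <- cur
    }
    defs
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") { defs <- flush(defs, cur); cur <- NULL; next }
    if (grepl("\t", ln)) {
      defs <- flush(defs, cur)
      parts <- strsplit(ln, "\t")[[1]]
      cur <- list(module_id = parts[1], name = parts[2], steps = list())
    } else {
      stop_if_not(!is.null(cur), "step line before any module header")
      kos <- trimws(strsplit(ln, ",")[[1]])
      stop_if_not(all(grepl("^K[0-9]{5}$", kos)),
                  sprintf("invalid KO identifier in module %s", cur$module_id))
      cur$steps[[length(cur$steps) + 1L]] <- kos
    }
  }
  flush(defs, cur)
}
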