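#' Parse a simple key-value configuration file
#'
#' The configuration dialect used for montages, band sets and simulator
#' settings: one `key: value ...` entry per line, values whitespace-separated,
#' `#` starts a comment, indented lines continue the previous key, and a key
#' repeated on several lines appends to its value list.
#'
#' @param path path to the configuration file.
#' @return named list; each element a character vector of tokens.
#' @keywords internal
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  out <- list()
  current <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln) && !is.null(current)) {
      out[[current]] <- c(out[[current]], strsplit(trimws(ln), "\\s+")[[1]])
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 0L)
      stop("malformed config line (expected 'key: value'): ", sQuote(ln))
    current <- m[2]
    tokens <- if (nzchar(trimws(m[3]))) strsplit(trimws(m[3]), "\\s+")[[1]] else character(0)
    out[[current]] <- c(out[[current]], tokens)
  }
  out
}

config_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

config_num <- function(cfg, key, default = NULL) {
  v <- config_get(cfg, key, default)
  if (is.null(v)) return(NULL)
  out <- suppressWarnings(as.numeric(v))
  if (anyNA(out)) stop("config key ", sQuote(key), " is not numeric: ",
                       paste(v, collapse = " "))
  out
}
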