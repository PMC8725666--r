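#' Read a two-class ARFF file
#'
#' Parses a dense-dialect ARFF file containing numeric feature attributes and
#' exactly one nominal class attribute (conventionally, but not necessarily,
#' declared last). This is the format of the classic gene-expression
#' benchmarks (e.g. the 77 x 7,129 DLBCL matrix) that motivate the package.
#'
#' Restrictions are deliberate and enforced with explicit errors: the sparse
#' ARFF dialect is rejected, missing values (\code{?}) are rejected (the
#' targeted benchmarks are complete matrices and no imputation policy is
#' assumed), and class attributes with more than two values raise an
#' unsupported-task error, since every method in the package is binary.
#'
#' @param path Path to an ARFF file.
#' @param positive_label Optional name of the class value to treat as
#'   positive. When omitted the rarer class is designated positive (the usual
#'   minority-positive convention); a count tie is broken in favour of the
#'   first-declared nominal value.
#' @return A [dataset()] with one feature per numeric attribute, in
#'   declaration order.
#' @seealso [write_arff()]
#' @export
read_arff <- function(path, positive_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n_lines <- length(lines)

  perr <- function(i, msg) stop(sprintf("ARFF parse error at line %d: %s", i, msg))

  attr_names <- character(0)
  attr_types <- list()   # NULL (numeric) or character vector of nominal values
  data_start <- NA_integer_

  i <- 0L
  while (i < n_lines) {
    i <- i + 1L
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "%")) next
    low <- tolower(ln)
    if (startsWith(low, "@relation")) next
    if (startsWith(low, "@attribute")) {
      rest <- trimws(substr(ln, nchar("@attribute") + 1L, nchar(ln)))
      parsed <- parse_attribute(rest)
      if (is.null(parsed)) perr(i, paste0("cannot parse attribute declaration '", ln, "'"))
      attr_names <- c(attr_names, parsed$name)
      attr_types <- c(attr_types, list(parsed$values))  # NULL for numeric
      next
    }
    if (startsWith(low, "@data")) { data_start <- i + 1L; break }
    perr(i, paste0("unexpected header line '", ln, "'"))
  }
  if (is.na(data_start)) perr(n_lines, "no @data section found")
  if (length(attr_names) < 2L) perr(data_start - 1L, "need at least one feature and a class attribute")
  if (anyDuplicated(attr_names)) stop("duplicate attribute names in ", path)

  nominal <- !vapply(attr_types, is.null, logical(1))
  if (sum(nominal) == 0L) stop("no nominal class attribute declared")
  if (sum(nominal) > 1L)
    stop("type error: ", sum(nominal), " nominal attributes declared; expected ",
         "numeric features plus a single nominal class attribute")
  class_idx <- which(nominal)
  class_values <- attr_types[[class_idx]]
  if (length(class_values) != 2L)
    stop("unsupported task: class attribute '", attr_names[class_idx], "' has ",
         length(class_values), " values; only two-class problems are supported")

  n_attr <- length(attr_names)
  rows <- vector("list", n_lines)
  labs <- character(0)
  nr <- 0L
  for (j in data_start:n_lines) {
    if (j > n_lines) break
    ln <- trimws(lines[[j]])
    if (ln == "" || startsWith(ln, "%")) next
    if (startsWith(ln, "{"))
      perr(j, "sparse ARFF dialect is not supported")
    vals <- split_csv_quoted(ln)
    if (length(vals) != n_attr)
      perr(j, sprintf("expected %d values, found %d", n_attr, length(vals)))
    if (any(vals == "?"))
      perr(j, "missing value '?' (complete matrices are required)")
    lab <- vals[class_idx]
    if (!lab %in% class_values)
      perr(j, paste0("class value '", lab, "' not among declared values"))
    num <- suppressWarnings(as.numeric(vals[-class_idx]))
    if (anyNA(num)) {
      bad <- vals[-class_idx][which(is.na(num))[1L]]
      perr(j, paste0("type error: non-numeric feature value '", bad, "'"))
    }
    nr <- nr + 1L
    rows[[nr]] <- num
    labs[nr] <- lab
  }
  if (nr == 0L) perr(n_lines, "no data rows")
  feat <- do.call(rbind, rows[seq_len(nr)])
  colnames(feat) <- attr_names[-class_idx]

  if (is.null(positive_label)) {
    counts <- vapply(class_values, function(v) sum(labs == v), numeric(1))
    # tie broken by declaration order (class_values order)
    positive_label <- class_values[which.min(counts)]
  }
  dataset(feat, labs, positive_label = positive_label)
}

#' Write a dataset to a dense ARFF file
#'
#' Numeric values are written at full \code{\%.17g} precision so that
#' \code{read_arff(write_arff(d))} reproduces \code{d} exactly (feature
#' names, values, labels and positive-class designation). The positive class
#' value is declared first in the class attribute, which makes the reader's
#' tie-break reproduce the designation even for balanced data.
#'
#' @param data A [dataset()].
#' @param path Output file path.
#' @param relation Relation name written to the \code{@relation} line.
#' @return \code{path}, invisibly.
#' @export
write_arff <- function(data, path, relation = "costlearn") {
  stopifnot(inherits(data, "costlearn_dataset"))
  neg <- setdiff(unique(data$labels), data$positive_label)
  class_name <- if ("class" %in% colnames(data$features)) "class_attr" else "class"
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("@relation ", arff_quote(relation)), con)
  for (nm in colnames(data$features))
    writeLines(paste0("@attribute ", arff_quote(nm), " numeric"), con)
  writeLines(paste0("@attribute ", arff_quote(class_name), " {",
                    arff_quote(data$positive_label), ",", arff_quote(neg), "}"), con)
  writeLines("@data", con)
  vals <- matrix(sprintf("%.17g", data$features), nrow = nrow(data$features))
  body <- paste0(apply(vals, 1L, paste, collapse = ","), ",",
                 vapply(data$labels, arff_quote, character(1)))
  writeLines(body, con)
  invisible(path)
}

# Quote an ARFF identifier/value only when needed.
arff_quote <- function(x) {
  if (grepl("[ ,{}'\"%\t]", x)) paste0("'", gsub("'", "\\\\'", x), "'") else x
}

# Parse "<name> <type>" from an @attribute declaration; returns NULL on failure.
parse_attribute <- function(rest) {
  if (startsWith(rest, "'") || startsWith(rest, "\"")) {
    q <- substr(rest, 1L, 1L)
    end <- regexpr(paste0("(?<!\\\\)", q), substr(rest, 2L, nchar(rest)), perl = TRUE)
    if (end < 0L) return(NULL)
    name <- gsub(paste0("\\\\", q), q, substr(rest, 2L, end))
    type <- trimws(substr(rest, end + 2L, nchar(rest)))
  } else {
    m <- regexpr("[ \t]", rest)
    if (m < 0L) return(NULL)
    name <- substr(rest, 1L, m - 1L)
    type <- trimws(substr(rest, m + 1L, nchar(rest)))
  }
  if (name == "") return(NULL)
  low <- tolower(type)
  if (low %in% c("numeric", "real", "integer"))
    return(list(name = name, values = NULL))
  if (startsWith(type, "{") && endsWith(type, "}")) {
    inner <- substr(type, 2L, nchar(type) - 1L)
    vals <- trimws(split_csv_quoted(inner))
    vals <- vapply(vals, arff_unquote, character(1), USE.NAMES = FALSE)
    if (length(vals) == 0L) return(NULL)
    return(list(name = name, values = vals))
  }
  # dates, strings, relational attributes: not meaningful for expression data
  stop("type error: unsupported attribute type '", type, "' for attribute '",
       name, "' (numeric features plus one nominal class attribute expected)")
}

arff_unquote <- function(x) {
  if (nchar(x) >= 2L && ((startsWith(x, "'") && endsWith(x, "'")) ||
                         (startsWith(x, "\"") && endsWith(x, "\"")))) {
    q <- substr(x, 1L, 1L)
    gsub(paste0("\\\\", q), q, substr(x, 2L, nchar(x) - 1L))
  } else x
}

# Split a comma-separated record, honouring single/double quotes.
split_csv_quoted <- function(line) {
  if (!grepl("['\"]", line))
    return(trimws(strsplit(line, ",", fixed = TRUE)[[1L]]))
  chars <- strsplit(line, "")[[1L]]
  out <- character(0)
  buf <- character(0)
  quote_ch <- ""
  k <- 1L
  while (k <= length(chars)) {
    ch <- chars[k]
    if (quote_ch != "") {
      if (ch == "\\" && k < length(chars) && chars[k + 1L] == quote_ch) {
        buf <- c(buf, quote_ch); k <- k + 1L
      } else if (ch == quote_ch) quote_ch <- ""
      else buf <- c(buf, ch)
    } else if (ch %in% c("'", "\"")) quote_ch <- ch
    else if (ch == ",") { out <- c(out, paste(buf, collapse = "")); buf <- character(0) }
    else buf <- c(buf, ch)
    k <- k + 1L
  }
  trimws(c(out, paste(buf, collapse = "")))
}
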