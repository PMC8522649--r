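# Readers and writers. TSV with explicit headers is the canonical dialect;
# CSV is accepted on ingest (by extension). Regions and genes are always
# matched by id/symbol, never by positional order. write(read(x)) preserves
# values to full double precision.

io_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

read_table_checked <- function(path, required = NULL) {
  if (!file.exists(path)) stop_mstx("file not found: %s", path)
  df <- utils::read.delim(path, sep = io_sep(path), stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_mstx("%s: missing required column(s): %s", path,
              paste(miss, collapse = ", "))
  df
}

#' Write / read a numeric matrix as TSV
#'
#' First column holds row ids (`id_col`), remaining columns are the matrix
#' columns. Values round-trip at full double precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path (`.tsv` or `.csv`).
#' @param id_col name of the id column (default `"id"`).
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), apply(m, 2, fmt_num),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = io_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv()`: the numeric matrix (row ids from the first
#'   column). Duplicate row or column ids are an error.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_table_checked(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_mstx("%s: duplicate row id(s): %s", path,
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- names(df)[-1]
  if (anyDuplicated(cn))
    stop_mstx("%s: duplicate column id(s): %s", path,
              paste(unique(cn[duplicated(cn)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m) && !anyNA(df[, -1]))
    stop_mstx("%s: non-numeric cells", path)
  dimnames(m) <- list(ids, cn)
  m
}

#' Read a regions x genes expression matrix
#'
#' TSV/CSV with region ids in the first column and gene symbols as the
#' header. Duplicated gene symbols or region ids and non-numeric cells are
#' errors naming the offender; missing values are not allowed.
#'
#' @param path input path.
#' @return numeric matrix, regions x genes.
#' @export
read_expression_matrix <- function(path) {
  m <- read_matrix_tsv(path)
  if (anyNA(m)) stop_mstx("%s: missing expression values", path)
  m
}

#' Write / read a cohort feature table
#'
#' Long-format features TSV (subject_id, region_id, feature, value) plus a
#' metadata TSV (subject_id, group, age, sex, education, batch,
#' memory_score). Every subject must have a value for every region x
#' feature combination.
#'
#' @param cohort an `ms_cohort`.
#' @param features_path,meta_path output paths.
#' @export
write_feature_table <- function(cohort, features_path, meta_path) {
  stopifnot(inherits(cohort, "ms_cohort"))
  x <- cohort$features
  dn <- dimnames(x)
  long <- data.frame(
    subject_id = rep(dn[[1]], times = length(dn[[2]]) * length(dn[[3]])),
    region_id = rep(rep(dn[[2]], each = length(dn[[1]])), times = length(dn[[3]])),
    feature = rep(dn[[3]], each = length(dn[[1]]) * length(dn[[2]])),
    value = fmt_num(as.vector(x)),
    stringsAsFactors = FALSE)
  utils::write.table(long, features_path, sep = io_sep(features_path),
                     quote = FALSE, row.names = FALSE)
  meta <- cohort$meta
  meta$memory_score <- fmt_num(meta$memory_score)
  utils::write.table(meta, meta_path, sep = io_sep(meta_path),
                     quote = FALSE, row.names = FALSE)
  invisible(features_path)
}

#' @rdname write_feature_table
#' @return `read_feature_table()`: an `ms_cohort` (features array + meta).
#' @export
read_feature_table <- function(features_path, meta_path) {
  long <- read_table_checked(features_path,
                             c("subject_id", "region_id", "feature", "value"))
  meta <- read_table_checked(meta_path, c("subject_id", "group"))
  subs <- unique(long$subject_id)
  regs <- unique(long$region_id)
  feats <- unique(long$feature)
  vocab <- feature_vocabulary()
  unknown <- setdiff(feats, vocab)
  if (length(unknown))
    stop_mstx("%s: unknown feature name(s): %s (expected among %s)",
              features_path, paste(unknown, collapse = ", "),
              paste(vocab, collapse = ", "))
  if (nrow(long) != length(subs) * length(regs) * length(feats))
    stop_mstx("%s: incomplete feature table (need every subject x region x feature)",
              features_path)
  x <- array(NA_real_, dim = c(length(subs), length(regs), length(feats)),
             dimnames = list(subs, regs, feats))
  x[cbind(match(long$subject_id, subs), match(long$region_id, regs),
          match(long$feature, feats))] <- as.numeric(long$value)
  if (anyNA(x)) stop_mstx("%s: missing feature values after ingest", features_path)
  if (!setequal(meta$subject_id, subs))
    stop_mstx("metadata subjects do not match the feature table")
  meta <- meta[match(subs, meta$subject_id), , drop = FALSE]
  rownames(meta) <- NULL
  if ("memory_score" %in% names(meta))
    meta$memory_score <- suppressWarnings(as.numeric(meta$memory_score))
  structure(list(features = x, meta = meta, truth = NULL, config = NULL),
            class = "ms_cohort")
}

#' Read / write gene sets
#'
#' A gene set file is either one symbol per line, or a two-column TSV
#' (`set`, `symbol`) holding several named sets.
#'
#' @param path input path.
#' @return a character vector (single set) or a named list of character
#'   vectors (two-column form).
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop_mstx("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (grepl("\t|,", first)) {
    df <- read_table_checked(path, c("set", "symbol"))
    return(split(df$symbol, df$set))
  }
  lines <- readLines(path)
  lines[nzchar(lines)]
}

#' @rdname read_gene_set
#' @param genes character vector of symbols.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then symbols.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_mstx("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop_mstx("%s: malformed GMT line: %s", path,
                                     substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets)))
    stop_mstx("%s: duplicate set name(s)", path)
  sets
}

#' Read a region atlas table
#'
#' Requires `region_id`; optional name, hemisphere, and MNI x/y/z columns
#' are passed through.
#'
#' @param path input path.
#' @return data.frame with unique region ids.
#' @export
read_region_atlas <- function(path) {
  df <- read_table_checked(path, "region_id")
  if (anyDuplicated(df$region_id))
    stop_mstx("%s: duplicate region id(s)", path)
  df
}

#' Read / write a flat key-value configuration file
#'
#' Minimal flat dialect: one `key: value` (or `key = value`) per line, `#`
#' comments, no nesting. Values are parsed as logical (`true`/`false`),
#' numeric when possible, comma-separated vectors otherwise strings. JSON
#' configs (`.json`) are also accepted.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_mstx("config not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:=]+)[:=](.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad))
    stop_mstx("%s: unparseable line(s): %s", path, paste(bad, collapse = "; "))
  out <- lapply(kv, function(m) parse_config_value(trimws(m[3])))
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}

parse_config_value <- function(v) {
  if (grepl(",", v)) return(unlist(lapply(trimws(strsplit(v, ",")[[1]]),
                                          parse_config_value)))
  if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
  if (tolower(v) %in% c("null", "")) return(NULL)
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' @rdname read_config
#' @param config named list of scalar/vector values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, ": ", paste(v, collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
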