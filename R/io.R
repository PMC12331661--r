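# Readers and writers for the tabular interchange formats.
# Genotype CSV dialect: comma-separated, UTF-8, first column the variety id,
# remaining columns one marker each with -1/+1 codes.

#' Write / read a QTN map as TSV
#'
#' Columns: `marker_id`, `chrom`, `pos_bp`, one effect column per
#' environment.
#'
#' @param qtn_map A `qtn_map`.
#' @param path File path.
#' @return `read_qtn_map()` returns a `qtn_map`; the writer returns the path
#'   invisibly.
#' @export
write_qtn_map <- function(qtn_map, path) {
  utils::write.table(qtn_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_qtn_map
#' @export
read_qtn_map <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  class(out) <- c("qtn_map", "data.frame")
  validate_qtn_map(out)
  out
}

#' Write / read a germplasm panel as CSV
#'
#' Header row of marker ids (first cell `variety_id`), one row per variety,
#' cells in -1/+1.
#'
#' @param panel Panel matrix.
#' @param path File path.
#' @param format `"csv"` (default) or `"vcf"` (read only).
#' @param qtn_map Optional `qtn_map` used to harmonize locus order; required
#'   for VCF input.
#' @return `read_panel()` returns the panel matrix (missing codes as `NA`,
#'   with a message reporting their count); the writer returns the path
#'   invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(variety_id = rownames(panel), panel,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, format = c("csv", "vcf"), qtn_map = NULL) {
  format <- match.arg(format)
  if (format == "vcf") return(read_panel_vcf(path, qtn_map))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  bad <- !(m %in% c(-1L, 1L) | is.na(m))
  if (any(bad)) stop("panel codes must be -1/+1; found ",
                     paste(unique(m[bad]), collapse = ", "))
  harmonize_panel(m, qtn_map)
}

read_panel_vcf <- function(path, qtn_map) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF import requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", vcfR::getALT(v), fixed = TRUE)
  if (any(multi)) {
    stop("non-biallelic site(s): ",
         paste(vcfR::getID(v)[multi], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v)          # markers x samples
  gt <- sub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% "0/0"] <- -1L
  code[gt %in% "1/1"] <- 1L
  m <- t(code)                       # varieties x markers
  n_miss <- sum(is.na(m))
  if (n_miss > 0) {
    message(n_miss, " heterozygous or missing call(s) set to NA")
  }
  harmonize_panel(m, qtn_map)
}

harmonize_panel <- function(m, qtn_map) {
  if (is.null(qtn_map)) return(m)
  miss <- setdiff(qtn_map$marker_id, colnames(m))
  if (length(miss)) {
    stop("markers in map absent from panel: ", paste(miss, collapse = ", "))
  }
  m[, qtn_map$marker_id, drop = FALSE]
}

#' Write / read a long-format phenotype table as CSV
#'
#' Columns `environment`, `block`, `variety_id`, `value`.
#'
#' @param pheno Phenotype table.
#' @param path File path.
#' @return `read_pheno()` returns the table; the writer returns the path
#'   invisibly.
#' @export
write_pheno <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("environment", "block", "variety_id", "value")
  if (!all(need %in% colnames(df))) {
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$value))) stop("non-finite phenotype values")
  df
}

#' Write a MAS model as TSV
#'
#' Body columns `marker_id`, `effect`, `superior_code`; header comment lines
#' carry environment, intercept, r2 and the gv-floor switch.
#'
#' @param model A `mas_model`.
#' @param path File path.
#' @return `read_mas_model()` returns a `mas_model` (without fitted values);
#'   the writer returns the path invisibly.
#' @export
write_mas_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# environment: %s", model$environment),
               sprintf("# intercept: %.17g", model$intercept),
               sprintf("# r2: %.17g", model$r2),
               sprintf("# gv_floor: %s", model$gv_floor),
               sprintf("# n: %d", model$n)), con)
  utils::write.table(data.frame(marker_id = names(model$effects),
                                effect = unname(model$effects),
                                superior_code = unname(model$superior)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mas_model
#' @export
read_mas_model <- function(path) {
  hdr <- readLines(path, n = 5)
  get <- function(key) sub(sprintf("^# %s: ", key), "", grep(
    sprintf("^# %s:", key), hdr, value = TRUE))
  body <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  model <- structure(list(environment = get("environment"),
                          intercept = as.numeric(get("intercept")),
                          effects = stats::setNames(body$effect,
                                                    body$marker_id),
                          r2 = as.numeric(get("r2")),
                          gv_floor = as.logical(get("gv_floor")),
                          n = as.integer(get("n"))),
                     class = "mas_model")
  model$superior <- stats::setNames(as.integer(body$superior_code),
                                    body$marker_id)
  model
}
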