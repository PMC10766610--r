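#' @keywords internal
"_PACKAGE"

# Well classes of the arrayed screen. Library wells carry a pooled-guide
# knock-out; media/uninfected wells define the Firefly background used by the
# QC gate; plate_pos_ctrl wells carry per-plate positive-control (full rescue)
# guides; nontargeting_ctrl wells carry a non-targeting guide.
WELL_CLASSES <- c("library", "media_ctrl", "uninfected_ctrl",
                  "plate_pos_ctrl", "nontargeting_ctrl")

PLATE_WELL_COLUMNS <- c("plate_id", "replicate_id", "well_id", "gene_id",
                        "guide_ids", "well_class", "hibit_rlu", "firefly_rlu")

#' Parse and canonicalize 384-well identifiers
#'
#' Well identifiers follow 384-well geometry: row letter `A`-`P` followed by a
#' column number 1-24. Parsing is case-insensitive and tolerates missing zero
#' padding; the canonical form is upper-case with a two-digit column
#' (`"a1"` becomes `"A01"`).
#'
#' @param well_id Character vector of well identifiers.
#' @return Character vector of canonical well identifiers.
#' @examples
#' parse_well_id(c("a1", "P24", "h07"))
#' @export
parse_well_id <- function(well_id) {
  if (!is.character(well_id)) well_id <- as.character(well_id)
  x <- toupper(trimws(well_id))
  m <- regmatches(x, regexec("^([A-Z])([0-9]{1,2})$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed well_id: ", paste(unique(well_id[bad]), collapse = ", "))
  }
  row <- vapply(m, `[`, character(1), 2L)
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  out_of_range <- !(row %in% LETTERS[1:16]) | col < 1L | col > 24L
  if (any(out_of_range)) {
    stop("well_id outside 384-well geometry (rows A-P, columns 1-24): ",
         paste(unique(well_id[out_of_range]), collapse = ", "))
  }
  sprintf("%s%02d", row, col)
}

split_guides <- function(guide_ids) {
  strsplit(ifelse(is.na(guide_ids) | guide_ids == "", "", guide_ids),
           ";", fixed = TRUE)
}

#' Validate a plate-well table
#'
#' Checks the invariants of the screen's atomic observation: canonical well
#' identifiers, known well classes, non-negative luminescence values, and the
#' gene/guide annotation rules (library wells carry a gene and 1-6 pooled
#' guides; control wells carry neither).
#'
#' @param wells Data frame with the plate-well columns (see
#'   [read_plate_table()]).
#' @return The validated data frame with canonical `well_id`, invisibly
#'   usable downstream.
#' @export
validate_plate_wells <- function(wells) {
  missing <- setdiff(PLATE_WELL_COLUMNS, names(wells))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  wells$plate_id <- as.character(wells$plate_id)
  wells$replicate_id <- as.character(wells$replicate_id)
  wells$gene_id <- ifelse(is.na(wells$gene_id), "", as.character(wells$gene_id))
  wells$guide_ids <- ifelse(is.na(wells$guide_ids), "",
                            as.character(wells$guide_ids))
  wells$well_class <- as.character(wells$well_class)
  wells$well_id <- parse_well_id(wells$well_id)

  bad_class <- !(wells$well_class %in% WELL_CLASSES)
  if (any(bad_class)) {
    stop("unknown well_class in row(s) ",
         paste(which(bad_class), collapse = ", "), ": ",
         paste(unique(wells$well_class[bad_class]), collapse = ", "))
  }
  for (col in c("hibit_rlu", "firefly_rlu")) {
    v <- wells[[col]]
    if (!is.numeric(v)) stop("column ", col, " must be numeric")
    neg <- !is.na(v) & v < 0
    if (any(neg)) {
      stop("negative ", col, " in row(s) ",
           paste(which(neg), collapse = ", "))
    }
    if (anyNA(v)) {
      stop("missing ", col, " in row(s) ",
           paste(which(is.na(v)), collapse = ", "))
    }
  }
  is_lib <- wells$well_class == "library"
  n_guides <- lengths(split_guides(wells$guide_ids))
  bad_lib <- is_lib & (wells$gene_id == "" | n_guides < 1L | n_guides > 6L)
  if (any(bad_lib)) {
    stop("library well(s) without a gene_id or with a guide pool outside ",
         "1-6 guides in row(s) ", paste(which(bad_lib), collapse = ", "))
  }
  bad_ctrl <- !is_lib & wells$gene_id != ""
  if (any(bad_ctrl)) {
    stop("control well(s) with a non-empty gene_id in row(s) ",
         paste(which(bad_ctrl), collapse = ", "))
  }
  key <- paste(wells$plate_id, wells$replicate_id, wells$well_id)
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, replicate_id, well_id): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  wells
}

read_csv_commented <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = TRUE)
}

#' Read a plate-well table
#'
#' Reads a comma-separated, UTF-8 plate table with a mandatory header row
#' naming the columns `plate_id, replicate_id, well_id, gene_id, guide_ids,
#' well_class, hibit_rlu, firefly_rlu`. Guide pools are serialized as
#' semicolon-joined text in `guide_ids`. Lines starting with `#` are treated
#' as comments. Malformed rows abort the read with a message naming the rows;
#' nothing is silently dropped.
#'
#' @param path Path to the CSV file.
#' @return Data frame of validated plate wells (one row per well), with
#'   well identifiers canonicalized to upper-case zero-padded form.
#' @seealso [write_plate_table()], [validate_plate_wells()]
#' @export
read_plate_table <- function(path) {
  wells <- read_csv_commented(path)
  if (nrow(wells) == 0L) stop("empty plate table: ", path)
  validate_plate_wells(wells)
}

write_csv_commented <- function(df, path, comments = character()) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.12g", df[[j]])
  lines <- c(if (length(comments) > 0L) paste0("# ", comments),
             paste(names(out), collapse = ","),
             if (nrow(out) > 0L) do.call(paste, c(unname(out), sep = ",")))
  writeLines(lines, con = path, useBytes = FALSE)
  invisible(path)
}

#' Write a plate-well table
#'
#' @param wells Data frame of plate wells (validated on write).
#' @param path Output CSV path.
#' @param comments Optional character vector written as `#`-prefixed header
#'   comment lines (e.g. seed and configuration hash).
#' @return The path, invisibly.
#' @export
write_plate_table <- function(wells, path, comments = character()) {
  wells <- validate_plate_wells(wells)
  write_csv_commented(wells[PLATE_WELL_COLUMNS], path, comments)
}

#' Read a screen-library annotation
#'
#' Reads a two-column CSV (`gene_id,guide_id`, one guide per row) describing
#' which pooled guides target each gene, and counts genes and guides from the
#' distinct identifiers.
#'
#' @param path Path to the library CSV.
#' @return An object of class `screen_library`: a list with `genes` (named
#'   list mapping gene to guide identifiers), `n_genes` and `n_guides`.
#' @export
read_library <- function(path) {
  df <- read_csv_commented(path)
  if (nrow(df) == 0L) stop("empty library file: ", path)
  if (!all(c("gene_id", "guide_id") %in% names(df))) {
    stop("library file must have columns gene_id, guide_id")
  }
  df$gene_id <- as.character(df$gene_id)
  df$guide_id <- as.character(df$guide_id)
  key <- paste(df$gene_id, df$guide_id)
  if (anyDuplicated(key)) {
    stop("duplicate (gene_id, guide_id) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  genes <- split(df$guide_id, df$gene_id)
  new_screen_library(genes)
}

new_screen_library <- function(genes) {
  if (any(lengths(genes) < 1L)) stop("every gene needs at least one guide")
  structure(
    list(genes = genes,
         n_genes = length(genes),
         n_guides = sum(lengths(genes))),
    class = "screen_library")
}

#' @export
print.screen_library <- function(x, ...) {
  cat("screen_library:", x$n_genes, "genes,", x$n_guides, "guides",
      sprintf("(%.1f per gene)\n", x$n_guides / x$n_genes))
  invisible(x)
}

#' Write a screen-library annotation
#'
#' @param library A `screen_library` object.
#' @param path Output CSV path.
#' @param comments Optional `#`-prefixed header comments.
#' @return The path, invisibly.
#' @export
write_library <- function(library, path, comments = character()) {
  stopifnot(inherits(library, "screen_library"))
  df <- data.frame(
    gene_id = rep(names(library$genes), lengths(library$genes)),
    guide_id = unlist(library$genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_csv_commented(df, path, comments)
}

GENE_SCORE_COLUMNS <- c("gene_id", "rsa_log10p", "max_rel_change",
                        "n_wells_used", "qc_pass")

#' Write gene-level screen scores
#'
#' One row per gene with columns `gene_id, rsa_log10p, max_rel_change,
#' n_wells_used, qc_pass` in that fixed order. Numeric values round-trip at
#' 12 significant digits.
#'
#' @param scores Data frame of gene scores (as returned by [score_genes()]).
#' @param path Output CSV path.
#' @param comments Optional `#`-prefixed header comments.
#' @return The path, invisibly.
#' @export
write_gene_scores <- function(scores, path, comments = character()) {
  if (is.null(scores) || nrow(scores) == 0L) {
    stop("scores must be non-empty")
  }
  missing <- setdiff(GENE_SCORE_COLUMNS, names(scores))
  if (length(missing) > 0L) {
    stop("missing gene-score column(s): ", paste(missing, collapse = ", "))
  }
  write_csv_commented(scores[GENE_SCORE_COLUMNS], path, comments)
}

#' Read gene-level screen scores
#'
#' @param path Path to a gene-score CSV written by [write_gene_scores()].
#' @return Data frame of gene scores.
#' @export
read_gene_scores <- function(path) {
  df <- read_csv_commented(path)
  missing <- setdiff(GENE_SCORE_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("missing gene-score column(s): ", paste(missing, collapse = ", "))
  }
  df$gene_id <- as.character(df$gene_id)
  df$qc_pass <- as.logical(df$qc_pass)
  df
}
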