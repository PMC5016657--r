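#' Read a GENEPOP genotype file
#'
#' Parses the classic GENEPOP dialect: a title line, one locus name per line
#' (or a single comma-separated line), `POP` markers delimiting samples, and
#' per-individual rows `id ,  aabb aabb ...` with 2- or 3-digit allele codes
#' concatenated per locus. `00`/`000` (or `0000`/`000000` for the diploid
#' pair) encodes a missing genotype. POP blocks become study-cell labels
#' `pop_1 ... pop_k` unless a sidecar table of per-individual cells and
#' coordinates overrides them.
#'
#' @param path file path.
#' @param cells optional data.frame with columns `id`, `cell`, `x`, `y`
#'   overriding POP-derived cell labels and supplying coordinates.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, cells = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3) stop("GENEPOP file too short")
  is_pop <- toupper(trimws(lines)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP marker found")
  locus_lines <- trimws(lines[2:(first_pop - 1)])
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L == 0) stop("no locus names found")
  ids <- character(); cell <- character()
  a1 <- integer(); a2 <- integer()
  pop <- 0L
  for (i in first_pop:length(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (toupper(trimws(ln)) == "POP") { pop <- pop + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("line %d: expected 'id , genotypes'", i))
    id <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    geno <- geno[nzchar(geno)]
    if (length(geno) != L)
      stop(sprintf("line %d: %d genotype fields, expected %d loci",
                   i, length(geno), L))
    w <- unique(nchar(geno))
    if (length(w) != 1 || !w %in% c(4L, 6L))
      stop(sprintf("line %d: malformed allele width (fields must be 4 or 6 digits)", i))
    half <- w / 2
    g1 <- as.integer(substr(geno, 1, half))
    g2 <- as.integer(substr(geno, half + 1, w))
    if (anyNA(g1) || anyNA(g2))
      stop(sprintf("line %d: non-numeric allele code", i))
    miss <- g1 == 0L | g2 == 0L
    g1[miss] <- NA; g2[miss] <- NA
    ids <- c(ids, id)
    cell <- c(cell, paste0("pop_", pop))
    a1 <- c(a1, g1); a2 <- c(a2, g2)
  }
  n <- length(ids)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  A1 <- matrix(a1, n, L, byrow = TRUE)
  A2 <- matrix(a2, n, L, byrow = TRUE)
  coords <- NULL
  if (!is.null(cells)) {
    m <- match(ids, as.character(cells$id))
    if (anyNA(m)) stop("sidecar table missing ids: ",
                       paste(utils::head(ids[is.na(m)]), collapse = ", "))
    cell <- as.character(cells$cell)[m]
    if (all(c("x", "y") %in% names(cells)))
      coords <- cbind(cells$x[m], cells$y[m])
  }
  genotype_dataset(ids, loci, A1, A2, cell, coords)
}

#' Write a GENEPOP genotype file
#'
#' Inverse of [read_genepop()]: one POP block per study cell (cells in first
#' appearance order), allele codes zero-padded to a fixed width, missing
#' genotypes as `0000`/`000000`.
#'
#' @param d a [genotype_dataset()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @param digits 2 or 3, allele-code width.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(d, path, title = "landgen export", digits = 3) {
  stopifnot(digits %in% c(2, 3))
  mx <- suppressWarnings(max(d$a1, d$a2, na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^digits)
    stop("allele codes too wide for ", digits, "-digit GENEPOP")
  fmt <- paste0("%0", digits, "d")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, d$loci), con)
  for (cl in unique(d$cell)) {
    writeLines("POP", con)
    for (i in which(d$cell == cl)) {
      g1 <- d$a1[i, ]; g2 <- d$a2[i, ]
      g1[is.na(g1)] <- 0L; g2[is.na(g2)] <- 0L
      writeLines(paste0(d$individuals[i], " ,  ",
                        paste0(sprintf(fmt, g1), sprintf(fmt, g2),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read genotypes from the individuals CSV dialect
#'
#' Columns: `id`, `cell`, `x`, `y`, then one column per locus holding
#' `"a1/a2"` with `"."` for a missing genotype.
#'
#' @param path CSV file path.
#' @return a [genotype_dataset()].
#' @export
read_individuals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("id", "cell", "x", "y")
  if (!all(fixed %in% names(df)))
    stop("individuals CSV needs columns id, cell, x, y")
  loci <- setdiff(names(df), fixed)
  if (!length(loci)) stop("no locus columns found")
  n <- nrow(df)
  A1 <- A2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    v <- as.character(df[[loci[j]]])
    miss <- v == "." | !nzchar(v) | is.na(v)
    parts <- strsplit(v[!miss], "/", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("locus ", loci[j], ": genotype entries must be 'a1/a2' or '.'")
    A1[!miss, j] <- as.integer(vapply(parts, `[`, "", 1))
    A2[!miss, j] <- as.integer(vapply(parts, `[`, "", 2))
  }
  genotype_dataset(df$id, loci, A1, A2, df$cell, cbind(df$x, df$y))
}

#' Write genotypes to the individuals CSV dialect
#' @param d a [genotype_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_individuals_csv <- function(d, path) {
  out <- data.frame(id = d$individuals, cell = d$cell,
                    x = d$coords[, 1], y = d$coords[, 2],
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(d$loci)) {
    v <- ifelse(is.na(d$a1[, j]), ".",
                paste0(d$a1[, j], "/", d$a2[, j]))
    out[[d$loci[j]]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study-cell table
#'
#' CSV with columns `cell`, `x`, `y` and optionally `side` (side-of-barrier
#' label used by [barrier_indicator()]).
#'
#' @param path CSV path.
#' @return data.frame with unique cell labels.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell", "x", "y") %in% names(df)))
    stop("cell table needs columns cell, x, y")
  df$cell <- as.character(df$cell)
  if (anyDuplicated(df$cell)) stop("duplicate cell labels")
  df
}
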