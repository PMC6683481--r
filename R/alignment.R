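#' Protein alignment catalogs and residue markers
#'
#' A per-gene protein alignment maps four-digit alleles to amino-acid
#' residues per position. Positions use mature-protein numbering: leader
#' peptide residues are negative, the first mature residue is 1, and no
#' position 0 exists.
#'
#' File dialect (one or more gene blocks per file):
#' \preformatted{
#' #gene=DQB1 start=-32 ref=DQB1*05:01
#' DQB1*05:01<TAB>MSWKKALRIP...
#' DQB1*06:02<TAB>--------S-...
#' }
#' Symbols in allele rows: a letter is the residue, `-` means identical to
#' the reference, `*` unknown, `.` an alignment gap. Columns where the
#' reference has `.` carry no position number and are excluded from the
#' marker space (substitutions only).
#'
#' @name protein-alignment
NULL

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

new_alignment <- function(gene, start, ref, seqs) {
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment rows for gene ", gene, call. = FALSE)
  }
  if (!ref %in% names(seqs)) {
    stop("reference allele ", ref, " missing from alignment block",
         call. = FALSE)
  }
  ref_res <- strsplit(seqs[[ref]], "")[[1]]
  if (any(ref_res == "*")) {
    stop("reference sequence may not contain unknown residues ('*')",
         call. = FALSE)
  }
  # expand '-' (same as reference) into the reference residue
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  same <- mat == "-"
  mat[same] <- ref_res[col(mat)][same]
  bad <- !(mat %in% c(AA_CODES, "*", ".")) & !is.na(mat)
  if (any(bad)) {
    stop("unexpected alignment symbol(s): ",
         paste(unique(mat[bad]), collapse = " "), call. = FALSE)
  }
  # number non-gap reference columns, skipping 0
  is_pos <- ref_res != "."
  pos <- rep(NA_integer_, length(ref_res))
  run <- start + seq_len(sum(is_pos)) - 1L
  if (start < 0) run[run >= 0] <- run[run >= 0] + 1L
  if (start == 0) stop("start position may not be 0", call. = FALSE)
  pos[is_pos] <- run
  structure(list(gene = gene, start = start, reference = ref,
                 residues = mat, column_positions = pos),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %s: %d alleles, %d columns, positions %d..%d (ref %s)\n",
              x$gene, nrow(x$residues), ncol(x$residues),
              min(x$column_positions, na.rm = TRUE),
              max(x$column_positions, na.rm = TRUE), x$reference))
  invisible(x)
}

#' Read a protein alignment catalog
#'
#' @param path path to a file in the alignment dialect (see
#'   [protein-alignment]).
#' @return named list of `protein_alignment` objects, one per gene block.
#' @export
read_protein_alignment <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^#", lines)
  if (!length(heads)) stop("no '#gene=' header found in ", path,
                           call. = FALSE)
  blocks <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hd <- lines[heads[i]]
    get_field <- function(key) {
      m <- regmatches(hd, regexec(paste0(key, "=([^ ]+)"), hd))[[1]]
      if (length(m) < 2) stop("header missing ", key, ": ", hd,
                              call. = FALSE)
      m[2]
    }
    gene <- get_field("gene")
    start <- as.integer(get_field("start"))
    ref <- get_field("ref")
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop("malformed allele row in block ", gene, call. = FALSE)
    }
    seqs <- vapply(parts, `[`, "", 2)
    names(seqs) <- normalize_allele(vapply(parts, `[`, "", 1), quiet = TRUE)
    if (anyDuplicated(names(seqs))) {
      stop("duplicate allele row in block ", gene, call. = FALSE)
    }
    blocks[[gene]] <- new_alignment(gene, start, normalize_allele(ref), seqs)
  }
  blocks
}

#' Write a protein alignment catalog
#'
#' Re-encodes each allele against its block's reference (`-` where equal),
#' so write-then-read round-trips.
#'
#' @param catalog named list of `protein_alignment` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_alignment <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (al in catalog) {
    writeLines(sprintf("#gene=%s start=%d ref=%s", al$gene, al$start,
                       al$reference), con)
    ref_res <- al$residues[al$reference, ]
    for (name in rownames(al$residues)) {
      res <- al$residues[name, ]
      if (name != al$reference) {
        res[res == ref_res & res != "*"] <- "-"
      }
      writeLines(paste0(name, "\t", paste(res, collapse = "")), con)
    }
  }
  invisible(path)
}

#' Residue carried by an allele at a position
#'
#' @param a a `protein_alignment`.
#' @param allele allele name.
#' @param position signed nonzero mature-protein position.
#' @return single residue letter, or `NA` if unknown (`*`) or deleted (`.`).
#' @export
residue_at <- function(a, allele, position) {
  if (position == 0) {
    stop("position 0 does not exist (numbering runs ..., -2, -1, 1, 2, ...)",
         call. = FALSE)
  }
  allele <- normalize_allele(allele, quiet = TRUE)
  if (!allele %in% rownames(a$residues)) {
    near <- utils::head(rownames(a$residues)[order(utils::adist(
      allele, rownames(a$residues)))], 3)
    stop("allele ", allele, " not in ", a$gene, " alignment; nearest: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  col <- which(a$column_positions == position)
  if (!length(col)) {
    stop("position ", position, " outside the ", a$gene, " alignment span",
         call. = FALSE)
  }
  r <- unname(a$residues[allele, col])
  if (r %in% c("*", ".")) NA_character_ else r
}

#' Residue catalog per (gene, position)
#'
#' @param catalog named list of `protein_alignment` objects.
#' @return data frame with `gene`, `position`, `residues` (collapsed
#'   string of distinct known residues), `n_residues`.
#' @export
position_catalog <- function(catalog) {
  rows <- lapply(catalog, function(al) {
    cols <- which(!is.na(al$column_positions))
    data.frame(
      gene = al$gene,
      position = al$column_positions[cols],
      residues = vapply(cols, function(j) {
        r <- setdiff(unique(al$residues[, j]), c("*", "."))
        paste(sort(r), collapse = "")
      }, ""),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n_residues <- nchar(out$residues)
  rownames(out) <- NULL
  out
}

#' Build residue dosage markers from genotypes and an alignment catalog
#'
#' One binary residue marker per (gene, position, residue) with at least
#' two distinct residues at the position. A sample's residue dosage is the
#' number of its alleles carrying the residue; an unknown residue at either
#' allele makes the dosage missing at that position, and alleles absent
#' from the alignment make the sample missing at all of that gene's residue
#' markers (logged via a message).
#'
#' @param catalog named list of `protein_alignment` objects.
#' @param g genotype table.
#' @param cohort cohort table (defines sample order).
#' @return list with `dosage` (an `hla_dosage`) and `catalog` (the
#'   [position_catalog()] of the alignments used).
#' @export
build_residue_markers <- function(catalog, g, cohort) {
  missing_samples <- setdiff(unique(g$sample_id), cohort$sample_id)
  if (length(missing_samples)) {
    stop("genotyped sample(s) absent from cohort: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  samples <- cohort$sample_id[cohort$sample_id %in% g$sample_id]
  mats <- list()
  defs <- list()
  for (gene in names(catalog)) {
    al <- catalog[[gene]]
    sub <- g[g$gene == gene, ]
    if (!nrow(sub)) next
    known <- rownames(al$residues)
    unmatched <- setdiff(stats::na.omit(c(sub$allele1, sub$allele2)), known)
    if (length(unmatched)) {
      message(gene, ": ", length(unmatched),
              " genotyped allele(s) absent from alignment, samples set ",
              "missing there: ", paste(unmatched, collapse = ", "))
    }
    cols <- which(!is.na(al$column_positions))
    multi <- cols[vapply(cols, function(j) {
      length(setdiff(unique(al$residues[, j]), c("*", "."))) >= 2
    }, TRUE)]
    if (!length(multi)) next
    # residue lookup per allele x retained column
    res1 <- matrix(NA_character_, nrow(sub), length(multi))
    res2 <- res1
    a1 <- match(sub$allele1, known)
    a2 <- match(sub$allele2, known)
    res1[!is.na(a1), ] <- al$residues[a1[!is.na(a1)], multi, drop = FALSE]
    res2[!is.na(a2), ] <- al$residues[a2[!is.na(a2)], multi, drop = FALSE]
    res1[res1 %in% c("*", ".")] <- NA
    res2[res2 %in% c("*", ".")] <- NA
    for (jj in seq_along(multi)) {
      j <- multi[jj]
      pos <- al$column_positions[j]
      residues <- sort(setdiff(unique(al$residues[, j]), c("*", ".")))
      ids <- sprintf("%s_%d_%s", gene, pos, residues)
      m <- matrix(NA_real_, length(samples), length(residues),
                  dimnames = list(samples, ids))
      ok <- !is.na(res1[, jj]) & !is.na(res2[, jj])
      rws <- match(sub$sample_id[ok], samples)
      m[rws, ] <- 0
      m[cbind(rws, match(res1[ok, jj], residues))] <-
        m[cbind(rws, match(res1[ok, jj], residues))] + 1
      m[cbind(rws, match(res2[ok, jj], residues))] <-
        m[cbind(rws, match(res2[ok, jj], residues))] + 1
      mats[[length(mats) + 1L]] <- m
      defs[[length(defs) + 1L]] <- data.frame(
        marker_id = ids, kind = "residue", gene = gene,
        allele = NA_character_, position = pos, residue = residues,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(mats)) stop("no polymorphic positions found", call. = FALSE)
  d <- new_dosage(do.call(cbind, mats), do.call(rbind, defs))
  list(dosage = d, catalog = position_catalog(catalog))
}

#' Alleles carrying a residue at a position
#' @param a a `protein_alignment`.
#' @param position signed nonzero position.
#' @param residue residue letter.
#' @return character vector of allele names.
#' @export
carrier_alleles <- function(a, position, residue) {
  col <- which(a$column_positions == position)
  if (!length(col)) stop("position outside alignment span", call. = FALSE)
  rownames(a$residues)[a$residues[, col] == residue]
}
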