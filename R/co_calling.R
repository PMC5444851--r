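#' Construct a marker map
#'
#' An ordered SNP map: one row per marker with its chromosome and physical
#' position (1-based bp). Within a chromosome, physical positions must be
#' strictly increasing; a \code{pos_cM} column of genetic positions, when
#' present, must be non-decreasing and order-concordant with the physical
#' positions.
#'
#' @param df Data frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos_bp} and optionally \code{pos_cM}.
#' @param centromeres Optional data frame (\code{chrom}, \code{start_bp},
#'   \code{end_bp}) attached as an attribute.
#' @return A \code{marker_map}.
#' @export
marker_map <- function(df, centromeres = NULL) {
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(df)))
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$marker_id)) stop("duplicated marker ids")
  for (ch in unique(df$chrom)) {
    p <- df$pos_bp[df$chrom == ch]
    if (any(diff(p) <= 0))
      stop("physical positions not strictly increasing on ", ch)
    if (!is.null(df$pos_cM)) {
      g <- df$pos_cM[df$chrom == ch]
      if (any(diff(g) < 0))
        stop("genetic positions not concordant with physical order on ", ch)
    }
  }
  if (!is.null(centromeres)) attr(df, "centromeres") <- centromeres
  class(df) <- unique(c("marker_map", class(df)))
  df
}

#' Read a marker map from TSV
#'
#' Expected columns: \code{marker_id}, \code{chrom} (or \code{chromosome}),
#' \code{pos_bp}, optionally \code{pos_cM}.
#'
#' @param path File path.
#' @param centromere_path Optional TSV with columns \code{chrom},
#'   \code{start_bp}, \code{end_bp}.
#' @return A \code{marker_map}.
#' @export
read_marker_map <- function(path, centromere_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("chromosome" %in% names(df) && !"chrom" %in% names(df))
    names(df)[names(df) == "chromosome"] <- "chrom"
  cen <- if (!is.null(centromere_path))
    utils::read.delim(centromere_path, stringsAsFactors = FALSE)
  marker_map(df, centromeres = cen)
}

#' Construct a genotype matrix
#'
#' Backcross allele calls (which F1 allele was transmitted) for markers x
#' progeny. Codes are restricted to two allele codes plus \code{NA}.
#'
#' @param geno Character matrix, rows = markers (rownames = marker ids),
#'   columns = progeny.
#' @param map The matching \code{\link{marker_map}}.
#' @param codes The two allowed allele codes.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{geno}, \code{map}, \code{progeny}, \code{codes}.
#' @export
genotype_matrix <- function(geno, map, codes = c("A", "B")) {
  stopifnot(inherits(map, "marker_map"))
  if (nrow(geno) != nrow(map))
    stop("genotype rows (", nrow(geno), ") do not match map size (",
         nrow(map), ")")
  if (!is.null(rownames(geno)) && !identical(rownames(geno), map$marker_id))
    stop("genotype rownames do not match marker ids")
  bad <- !is.na(geno) & !(geno %in% codes)
  if (any(bad))
    stop("unknown allele code(s): ",
         paste(unique(geno[bad]), collapse = ", "))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("P%04d", seq_len(ncol(geno)))
  rownames(geno) <- map$marker_id
  structure(list(geno = geno, map = map, progeny = colnames(geno),
                 codes = codes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "markers x", ncol(x$geno),
      "progeny on", length(unique(x$map$chrom)), "chromosomes\n")
  invisible(x)
}

#' Write a genotype matrix as TSV
#'
#' Canonical plain-text exchange format: one row per marker with
#' \code{marker_id}, \code{chrom}, \code{pos_bp} (and \code{pos_cM} if
#' present), then one column per progeny with codes A/B/NA.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param path Output file path.
#' @export
write_genotype_table <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  meta <- gm$map[, intersect(c("marker_id", "chrom", "pos_bp", "pos_cM"),
                             names(gm$map)), drop = FALSE]
  out <- cbind(meta, as.data.frame(gm$geno, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' QC policy for genotype input
#'
#' @param drop_missing Drop progeny with any missing call.
#' @param check_duplicates Drop progeny whose duplicate-assay calls disagree
#'   (when duplicate assays are supplied).
#' @return A list of policy flags.
#' @export
qc_policy <- function(drop_missing = TRUE, check_duplicates = TRUE) {
  list(drop_missing = drop_missing, check_duplicates = check_duplicates)
}

#' Read a backcross genotype table with QC
#'
#' Reads the canonical TSV (see \code{\link{write_genotype_table}}), checks
#' allele codes and marker identity against the map, and applies the QC
#' policy: progeny with any missing call, or with any mismatch between
#' duplicate assays, are dropped. A QC report (kept/dropped counts with
#' reasons) is attached as the \code{"qc_report"} attribute.
#'
#' @param path File path.
#' @param map Optional \code{\link{marker_map}}; when \code{NULL} the map is
#'   taken from the file's metadata columns.
#' @param qc A \code{\link{qc_policy}}.
#' @param duplicates Optional duplicate-assay calls: a character matrix with
#'   rownames a subset of marker ids and the same progeny columns, compared
#'   call-for-call against the main assay.
#' @param codes The two allowed allele codes.
#' @return A \code{\link{genotype_matrix}} restricted to progeny passing QC.
#' @export
read_genotype_table <- function(path, map = NULL, qc = qc_policy(),
                                duplicates = NULL, codes = c("A", "B")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  meta_cols <- intersect(c("marker_id", "chrom", "pos_bp", "pos_cM"),
                         names(df))
  if (!"marker_id" %in% meta_cols) stop("file lacks a 'marker_id' column")
  if (is.null(map)) {
    map <- marker_map(df[, meta_cols, drop = FALSE])
  } else {
    if (!all(df$marker_id %in% map$marker_id))
      stop("marker id(s) absent from map: ",
           paste(utils::head(setdiff(df$marker_id, map$marker_id)),
                 collapse = ", "))
    df <- df[match(map$marker_id, df$marker_id), , drop = FALSE]
  }
  geno <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(geno) <- df$marker_id
  gm <- genotype_matrix(geno, map, codes = codes)
  apply_genotype_qc(gm, qc = qc, duplicates = duplicates)
}

#' Apply the QC policy to an in-memory genotype matrix
#'
#' @inheritParams read_genotype_table
#' @param gm A \code{\link{genotype_matrix}}.
#' @return The filtered \code{genotype_matrix} with a \code{"qc_report"}
#'   attribute.
#' @export
apply_genotype_qc <- function(gm, qc = qc_policy(), duplicates = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  drop_reason <- character(0)
  drop_id <- character(0)
  if (isTRUE(qc$drop_missing)) {
    miss <- colSums(is.na(gm$geno)) > 0
    drop_id <- c(drop_id, gm$progeny[miss])
    drop_reason <- c(drop_reason, rep("missing_data", sum(miss)))
  }
  if (isTRUE(qc$check_duplicates) && !is.null(duplicates)) {
    common <- intersect(rownames(duplicates), rownames(gm$geno))
    prog <- intersect(colnames(duplicates), gm$progeny)
    mm <- vapply(prog, function(pid) {
      a <- gm$geno[common, pid]; b <- duplicates[common, pid]
      any(!is.na(a) & !is.na(b) & a != b)
    }, logical(1))
    drop_id <- c(drop_id, prog[mm])
    drop_reason <- c(drop_reason, rep("duplicate_mismatch", sum(mm)))
  }
  keep <- !(gm$progeny %in% drop_id)
  if (!any(keep)) stop("no progeny left after QC")
  out <- genotype_matrix(gm$geno[, keep, drop = FALSE], gm$map,
                         codes = gm$codes)
  attr(out, "qc_report") <- list(
    n_input = length(gm$progeny), n_kept = sum(keep),
    dropped = data.frame(progeny = drop_id, reason = drop_reason,
                         stringsAsFactors = FALSE))
  out
}

#' Test 1:1 Mendelian segregation per marker
#'
#' Two-category chi-squared test of the backcross expectation that each F1
#' allele is transmitted to half the progeny, computed per marker on
#' non-missing calls. Failing markers are flagged, not removed.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param alpha Significance threshold.
#' @return Data frame with per-marker counts, chi-squared statistic
#'   (1 df), p-value and a \code{pass} flag (\code{NA} for markers with no
#'   informative calls).
#' @export
test_marker_segregation <- function(gm, alpha = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$geno) < 2L) stop("need at least 2 progeny")
  nA <- rowSums(gm$geno == gm$codes[1], na.rm = TRUE)
  nB <- rowSums(gm$geno == gm$codes[2], na.rm = TRUE)
  n <- nA + nB
  stat <- ifelse(n > 0, (nA - nB)^2 / n, NA_real_)
  pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  data.frame(marker_id = gm$map$marker_id, chrom = gm$map$chrom,
             n_A = nA, n_B = nB, statistic = stat, p_value = pval,
             pass = ifelse(is.na(pval), NA, pval >= alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call crossovers from a genotype matrix
#'
#' One crossover is called at every allele transition between adjacent
#' non-missing markers within a chromosome; its genetic position is the
#' mid-value of the two flanking markers on the genetic map, and its physical
#' position the mid-value in bp. Genetic positions are taken from the map's
#' \code{pos_cM} column, built with \code{\link{build_genetic_map}} when
#' absent.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param genetic_map Optional \code{marker_map} with \code{pos_cM}
#'   (e.g. from \code{\link{build_genetic_map}}); defaults to \code{gm$map}
#'   if it has genetic positions, else the Kosambi map estimated from
#'   \code{gm} itself.
#' @param label Population label carried through summaries.
#' @return An object of class \code{co_pop}: list with \code{calls} (data
#'   frame \code{progeny}, \code{chrom}, \code{left_marker},
#'   \code{right_marker}, \code{cM_mid}, \code{bp_mid}), \code{counts}
#'   (progeny x chromosome matrix), \code{n_progeny}, \code{map} and
#'   \code{chrom_len_cM}.
#' @export
call_crossovers <- function(gm, genetic_map = NULL, label = "pop") {
  stopifnot(inherits(gm, "genotype_matrix"))
  map <- if (!is.null(genetic_map)) genetic_map
         else if (!is.null(gm$map$pos_cM)) gm$map
         else build_genetic_map(gm)
  if (is.null(map$pos_cM)) stop("genetic map lacks 'pos_cM'")
  chroms <- unique(map$chrom)
  prog <- gm$progeny
  calls <- vector("list", length(chroms))
  counts <- matrix(0L, nrow = length(prog), ncol = length(chroms),
                   dimnames = list(prog, chroms))
  for (ci in seq_along(chroms)) {
    sel <- which(map$chrom == chroms[ci])
    sub <- gm$geno[sel, , drop = FALSE]
    acc <- list()
    for (pi in seq_along(prog)) {
      v <- sub[, pi]
      ok <- which(!is.na(v))
      if (length(ok) < 2L) next
      trans <- which(v[ok[-length(ok)]] != v[ok[-1L]])
      if (length(trans) == 0L) next
      li <- sel[ok[trans]]; ri <- sel[ok[trans + 1L]]
      acc[[length(acc) + 1L]] <- data.frame(
        progeny = prog[pi], chrom = chroms[ci],
        left_marker = map$marker_id[li], right_marker = map$marker_id[ri],
        cM_mid = (map$pos_cM[li] + map$pos_cM[ri]) / 2,
        bp_mid = (map$pos_bp[li] + map$pos_bp[ri]) / 2,
        stringsAsFactors = FALSE)
      counts[pi, ci] <- length(trans)
    }
    calls[[ci]] <- if (length(acc)) do.call(rbind, acc) else NULL
  }
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls))
    calls <- data.frame(progeny = character(0), chrom = character(0),
                        left_marker = character(0),
                        right_marker = character(0),
                        cM_mid = numeric(0), bp_mid = numeric(0))
  rownames(calls) <- NULL
  len <- vapply(chroms, function(ch) {
    g <- map$pos_cM[map$chrom == ch]
    max(g) - min(g)
  }, numeric(1))
  structure(list(label = label, calls = calls, counts = counts,
                 n_progeny = length(prog), map = map,
                 chrom_len_cM = stats::setNames(len, chroms)),
            class = "co_pop")
}

#' @export
print.co_pop <- function(x, ...) {
  cat("co_pop '", x$label, "': ", x$n_progeny, " progeny, ",
      nrow(x$calls), " crossovers on ", ncol(x$counts),
      " chromosomes\n", sep = "")
  invisible(x)
}

#' Summarise crossover counts per chromosome and genome-wide
#'
#' Gamete-scale means with standard errors, plus the meiosis scale obtained
#' by doubling (each meiosis yields four chromatids, of which the genotyped
#' progeny chromatid carries on average half the bivalent's COs, so the
#' per-meiosis mean is exactly twice the per-gamete mean; its SE is
#' 2 x gamete SD / sqrt(n)).
#'
#' @param pop A \code{\link{call_crossovers}} result.
#' @return Data frame with one row per chromosome plus a \code{"GENOME"} row:
#'   \code{n}, \code{mean_gamete}, \code{se_gamete}, \code{mean_meiosis},
#'   \code{se_meiosis}.
#' @export
summarize_counts <- function(pop) {
  stopifnot(inherits(pop, "co_pop"))
  if (pop$n_progeny < 1L) stop("empty population")
  per_chrom <- pop$counts
  genome <- rowSums(per_chrom)
  one <- function(v, name) {
    m <- mean(v); s <- stats::sd(v) / sqrt(length(v))
    data.frame(chrom = name, n = length(v), mean_gamete = m,
               se_gamete = s, mean_meiosis = 2 * m, se_meiosis = 2 * s,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(colnames(per_chrom), function(ch) one(per_chrom[, ch], ch)),
    list(one(genome, "GENOME"))))
  rownames(out) <- NULL
  out
}

#' Convert a supplementary XLSX genotyping table to the canonical TSV
#'
#' Best-effort ingester for published per-population genotyping workbooks:
#' expects one sheet whose leading columns identify the marker (id,
#' chromosome, physical position, in any of a few common spellings) followed
#' by one column per progeny. Allele-code dialects are declared explicitly,
#' never guessed: calls not in \code{names(code_map)} (after trimming) become
#' missing.
#'
#' @param path XLSX file path.
#' @param out_tsv Output TSV path.
#' @param sheet Sheet name or index.
#' @param code_map Named character vector mapping source codes to A/B,
#'   e.g. \code{c(A = "A", B = "B")}.
#' @return The output path, invisibly. Requires the \pkg{readxl} package.
#' @export
convert_supplementary_xlsx <- function(path, out_tsv, sheet = 1,
                                       code_map = c(A = "A", B = "B")) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("convert_supplementary_xlsx requires the 'readxl' package")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet),
                      stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("cannot find a column among: ",
                       paste(cands, collapse = ", "))
    i
  }
  i_id <- pick(c("marker_id", "marker", "snp", "snp_id", "locus"))
  i_ch <- pick(c("chrom", "chromosome", "chr", "linkage_group", "lg"))
  i_bp <- pick(c("pos_bp", "position", "position_bp", "physical_position",
                 "pos", "bp"))
  meta <- data.frame(marker_id = as.character(df[[i_id]]),
                     chrom = as.character(df[[i_ch]]),
                     pos_bp = as.numeric(df[[i_bp]]),
                     stringsAsFactors = FALSE)
  geno_cols <- setdiff(seq_along(df), c(i_id, i_ch, i_bp))
  geno <- as.matrix(df[, geno_cols, drop = FALSE])
  geno[] <- trimws(geno)
  geno[] <- unname(code_map[geno])
  o <- order(meta$chrom, meta$pos_bp)
  out <- cbind(meta[o, , drop = FALSE],
               as.data.frame(geno[o, , drop = FALSE],
                             stringsAsFactors = FALSE))
  utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_tsv)
}
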