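#' Read CNV calls from a BED-like file
#'
#' Expects four or more whitespace-delimited columns: chromosome, start, end,
#' copy-number status, with coordinates 0-based half-open. An optional fifth
#' column is taken as the sample identifier. SV type is inferred from the
#' copy-number status (0,1 -> DEL; 3,4 -> DUP); status 2 is rejected because a
#' diploid segment is not a CNV.
#'
#' @param path Path to the BED file.
#' @param sample_id Sample identifier used when the file has no sample column.
#' @param source Label recorded in the `source` column.
#' @return A CNV call table (see [cnv_calls()]).
#' @export
read_cnv_bed <- function(path, sample_id = "", source = "bed") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(cnv_calls())
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 4)) {
    stop("malformed BED row (fewer than 4 columns) at line ",
         which(ncols < 4)[1])
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  cn <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(cn))
  if (length(bad)) stop("malformed BED row (non-numeric field) at line ", bad[1])
  if (any(cn == 2L)) {
    stop("copy number 2 at line ", which(cn == 2L)[1],
         ": diploid state is not a CNV")
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) at line ", bad[1])
  }
  sid <- if (all(ncols >= 5)) vapply(fields, `[`, character(1), 5L) else sample_id
  cnv_calls(chrom = chrom, start = start, end = end, copy_number = cn,
            sample_id = sid, source = source)
}

#' Write CNV calls to a BED-like file
#'
#' Emits chromosome, start, end, copy-number status (0-based half-open), plus
#' the sample identifier as a fifth column when `sample_col = TRUE`.
#'
#' @param calls CNV call table.
#' @param path Output path.
#' @param sample_col Include the sample identifier column.
#' @return `path`, invisibly.
#' @export
write_cnv_bed <- function(calls, path, sample_col = FALSE) {
  validate_cnv_calls(calls)
  cols <- c("chrom", "start", "end", "copy_number",
            if (sample_col) "sample_id")
  utils::write.table(calls[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-sample genotyped CNV VCF
#'
#' Reads a VCF with symbolic `<DEL>`/`<DUP>` ALT alleles, an INFO `END` tag
#' and per-sample genotypes (typically the output of graph-genome joint
#' genotyping across a cohort). POS is converted from 1-based to the internal
#' 0-based half-open convention (`start = POS - 1`, `end = END`). Records
#' whose ALT is neither `<DEL>` nor `<DUP>` (inversions, breakends, ...) are
#' skipped and counted. Multi-allelic records are split into one record per
#' ALT allele. Records failing the site FILTER are retained with
#' `filter_pass = FALSE`.
#'
#' @param path Path to the VCF (plain or bgzipped).
#' @return A list of class `cnv_vcf` with elements `records` (data.frame:
#'   `chrom`, `start`, `end`, `svtype`, `filter`, `filter_pass`,
#'   `allele_index`), `gt` (record x sample genotype matrix), `ft` (record x
#'   sample per-genotype filter matrix, or `NULL` when the VCF has no FT
#'   field), `samples`, and `n_skipped` (non-DEL/DUP records dropped).
#' @export
read_cnv_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  info <- fix[, "INFO"]
  end_raw <- sub(".*(^|;)END=([0-9]+).*", "\\2", paste0(";", info))
  has_end <- grepl("(^|;)END=[0-9]+", info)
  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  gt_all <- if (ncol(v@gt) > 1) vcfR::extract.gt(v, element = "GT") else NULL
  ft_all <- if (ncol(v@gt) > 1 && any(grepl("(^|:)FT(:|$)", v@gt[, "FORMAT"])))
    vcfR::extract.gt(v, element = "FT") else NULL
  samples <- if (!is.null(gt_all)) colnames(gt_all) else character()

  rec <- list(); gt_rows <- list(); ft_rows <- list(); n_skipped <- 0L
  for (i in seq_len(n)) {
    alts <- alt_list[[i]]
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (!alt %in% c("<DEL>", "<DUP>")) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (!has_end[i]) {
        stop("record at ", fix[i, "CHROM"], ":", fix[i, "POS"],
             " has no INFO END tag")
      }
      filt <- fix[i, "FILTER"]
      rec[[length(rec) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"],
        start = as.integer(fix[i, "POS"]) - 1L,
        end = as.integer(end_raw[i]),
        svtype = if (alt == "<DEL>") "DEL" else "DUP",
        filter = filt,
        filter_pass = is.na(filt) || filt %in% c("PASS", "."),
        allele_index = j,
        stringsAsFactors = FALSE
      )
      gt_rows[[length(gt_rows) + 1L]] <- if (!is.null(gt_all)) gt_all[i, ] else NULL
      ft_rows[[length(ft_rows) + 1L]] <- if (!is.null(ft_all)) ft_all[i, ] else NULL
    }
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               svtype = character(), filter = character(),
               filter_pass = logical(), allele_index = integer())
  rownames(records) <- NULL
  gt <- if (length(gt_rows) && !is.null(gt_rows[[1]]))
    do.call(rbind, gt_rows) else NULL
  ft <- if (length(ft_rows) && !is.null(ft_rows[[1]]))
    do.call(rbind, ft_rows) else NULL
  if (!is.null(gt)) colnames(gt) <- samples
  if (!is.null(ft)) colnames(ft) <- samples
  structure(list(records = records, gt = gt, ft = ft, samples = samples,
                 n_skipped = n_skipped),
            class = "cnv_vcf")
}

# Internal: parse a diploid GT string into allele indices, or NULL for missing.
parse_gt <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  alleles <- strsplit(gt, "[/|]")[[1]]
  idx <- suppressWarnings(as.integer(alleles))
  if (any(is.na(idx) & alleles != ".")) stop("unknown genotype encoding: ", gt)
  idx[alleles == "."] <- NA_integer_
  idx
}

#' Extract one sample's PASS CNV calls from a genotyped VCF
#'
#' Emits one call per record at which the sample carries a non-reference
#' genotype and the genotype passes filtering (site FILTER is PASS, and the
#' per-genotype FT field, when present, is PASS). The genotype maps to
#' copy-number status as: DEL het -> 1, DEL hom-alt -> 0, DUP het -> 3,
#' DUP hom-alt -> 4.
#'
#' @param vcf A `cnv_vcf` object from [read_cnv_vcf()].
#' @param sample_id Sample name, present in the VCF.
#' @param require_pass Keep only calls passing site and genotype filters
#'   (default `TRUE`).
#' @return A CNV call table sorted by position.
#' @export
vcf_to_sample_calls <- function(vcf, sample_id, require_pass = TRUE) {
  if (!sample_id %in% vcf$samples) {
    stop("sample not present in VCF: ", sample_id)
  }
  rec <- vcf$records
  gts <- vcf$gt[, sample_id]
  fts <- if (!is.null(vcf$ft)) vcf$ft[, sample_id] else rep(NA_character_, nrow(rec))
  keep <- logical(nrow(rec)); cn <- integer(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    alleles <- parse_gt(gts[i])
    if (is.null(alleles)) next
    n_alt <- sum(alleles == rec$allele_index[i], na.rm = TRUE)
    if (n_alt == 0) next
    gt_pass <- rec$filter_pass[i] && (is.na(fts[i]) || fts[i] %in% c("PASS", "."))
    if (require_pass && !gt_pass) next
    cn[i] <- if (rec$svtype[i] == "DEL") {
      if (n_alt >= 2) 0L else 1L
    } else {
      if (n_alt >= 2) 4L else 3L
    }
    keep[i] <- TRUE
  }
  out <- cnv_calls(chrom = rec$chrom[keep], start = rec$start[keep],
                   end = rec$end[keep], copy_number = cn[keep],
                   sample_id = sample_id, source = "vcf")
  sort_calls(out)
}

#' Export consolidated calls as a PLINK six-column CNV file
#'
#' Writes the tabular format expected by PLINK's CNV module: family ID,
#' sample ID, chromosome, start, end, copy-number status, sorted by position.
#' Coordinates are converted to 1-based inclusive (`BP1 = start + 1`,
#' `BP2 = end`) and any `chr` prefix is stripped from chromosome names.
#' Family IDs are taken from the phenotype table when given and default to the
#' sample ID (the convention for cohorts without family structure).
#' Overlapping segments within one sample are refused, since downstream
#' association tools do not accept them.
#'
#' @param calls Consolidated CNV call table (cohort-wide, with `sample_id`).
#' @param path Output path.
#' @param phenotypes Optional phenotype table (see [read_phenotypes()])
#'   supplying `family_id`.
#' @return `path`, invisibly.
#' @export
to_plink_cnv <- function(calls, path, phenotypes = NULL) {
  validate_cnv_calls(calls)
  ov <- find_within_sample_overlaps(calls)
  if (nrow(ov)) {
    stop("overlapping CNV segments within sample(s) ",
         paste(unique(ov$sample_id), collapse = ", "),
         "; consolidate before export (e.g. ", ov$chrom[1], ":", ov$start1[1],
         "-", ov$end1[1], " overlaps ", ov$start2[1], "-", ov$end2[1], ")")
  }
  fid <- calls$sample_id
  if (!is.null(phenotypes)) {
    m <- match(calls$sample_id, phenotypes$sample_id)
    fid <- ifelse(is.na(m), calls$sample_id, phenotypes$family_id[m])
  }
  df <- data.frame(
    FID = fid,
    IID = calls$sample_id,
    CHR = sub("^chr", "", calls$chrom),
    BP1 = calls$start + 1L,
    BP2 = calls$end,
    CN = calls$copy_number,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$CHR, df$BP1, df$BP2, df$IID), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PLINK six-column CNV file
#'
#' Inverse of [to_plink_cnv()]: BP1/BP2 (1-based inclusive) are converted back
#' to 0-based half-open coordinates.
#'
#' @param path Path to the six-column file.
#' @param chrom_prefix Prefix to prepend to chromosome names (e.g. `"chr"`).
#' @return A CNV call table.
#' @export
read_plink_cnv <- function(path, chrom_prefix = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("FID", "IID", "CHR", "BP1", "BP2", "CN"),
                          colClasses = c("character", "character", "character",
                                         "integer", "integer", "integer"))
  if (nrow(df) == 0) return(cnv_calls())
  cnv_calls(chrom = paste0(chrom_prefix, df$CHR), start = df$BP1 - 1L,
            end = df$BP2, copy_number = df$CN, sample_id = df$IID,
            source = "plink")
}

# Internal: rows describing within-sample overlapping pairs (empty if none).
find_within_sample_overlaps <- function(calls) {
  out <- list()
  for (sid in unique(calls$sample_id)) {
    sub <- sort_calls(calls[calls$sample_id == sid, , drop = FALSE])
    if (nrow(sub) < 2) next
    same_chrom <- sub$chrom[-nrow(sub)] == sub$chrom[-1]
    ov <- which(same_chrom & sub$end[-nrow(sub)] > sub$start[-1])
    if (length(ov)) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, chrom = sub$chrom[ov],
        start1 = sub$start[ov], end1 = sub$end[ov],
        start2 = sub$start[ov + 1L], end2 = sub$end[ov + 1L],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), chrom = character(),
               start1 = integer(), end1 = integer(),
               start2 = integer(), end2 = integer())
}

#' Read a genome accessibility mask
#'
#' Reads a BED-like file whose extra column labels each interval with an
#' accessibility class: `P` (passed), `N` (reference is N), `L` (low
#' coverage), `H` (high coverage) or `Z` (zero mapping quality). The label is
#' taken from the fifth column when present, otherwise the fourth. Intervals
#' are returned sorted per chromosome; overlapping intervals with different
#' labels are an error. Adjacent same-label intervals are kept as given (the
#' reader does not transform its input).
#'
#' @param path Path to the mask BED.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`
#'   (0-based half-open), of class `mask_track`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("mask file needs at least 4 columns")
  label <- if (ncol(df) >= 5 && all(df[[5]] %in% MASK_CLASSES)) df[[5]] else df[[4]]
  mask <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                     end = as.integer(df[[3]]), label = as.character(label),
                     stringsAsFactors = FALSE)
  bad <- which(!mask$label %in% MASK_CLASSES)
  if (length(bad)) {
    stop("unknown mask class '", mask$label[bad[1]], "' at line ", bad[1],
         " (expected one of ", paste(MASK_CLASSES, collapse = ", "), ")")
  }
  if (any(!(mask$start >= 0 & mask$start < mask$end))) stop("invalid mask interval")
  ord <- order(mask$chrom, mask$start, mask$end)
  mask <- mask[ord, , drop = FALSE]
  rownames(mask) <- NULL
  same <- mask$chrom[-nrow(mask)] == mask$chrom[-1]
  ovl <- which(same & mask$end[-nrow(mask)] > mask$start[-1])
  diff_lab <- ovl[mask$label[ovl] != mask$label[ovl + 1L]]
  if (length(diff_lab)) {
    stop("overlapping mask intervals with different labels at ",
         mask$chrom[diff_lab[1]], ":", mask$start[diff_lab[1] + 1L])
  }
  class(mask) <- c("mask_track", class(mask))
  mask
}

MASK_CLASSES <- c("P", "N", "L", "H", "Z")

#' Write a genome accessibility mask
#'
#' @param mask Mask table (`chrom`, `start`, `end`, `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a case/control phenotype table
#'
#' Tab-separated with header; requires columns `sample_id` and `status`
#' (values `case`/`control`); optional `family_id` (defaults to the sample ID)
#' and `group` (ancestry/ethnicity label, e.g. `AA`, `Hispanic`, `NHW`,
#' `Other`; defaults to `Other`).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `sample_id`, `family_id`, `status`,
#'   `group`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(df))) {
    stop("phenotype table needs columns sample_id and status")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in phenotype table")
  if (!all(df$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'")
  }
  if (is.null(df$family_id)) df$family_id <- df$sample_id
  if (is.null(df$group)) df$group <- "Other"
  df[, c("sample_id", "family_id", "status", "group")]
}

#' Write a phenotype table
#'
#' @param phenotypes Phenotype table (see [read_phenotypes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a bedGraph-style depth track
#'
#' Four columns: chromosome, start, end, mean depth over the interval
#' (0-based half-open).
#'
#' @param path Path to the bedGraph file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `depth`.
#' @export
read_depth_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "depth"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  df
}

#' Write a bedGraph-style depth track
#'
#' @param track Depth track (`chrom`, `start`, `end`, `depth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a (multi-sample) CNV VCF with symbolic alleles
#'
#' Emits minimal VCF 4.2 with `<DEL>`/`<DUP>` symbolic ALT alleles, INFO
#' `END`/`SVTYPE` tags, and optional per-sample `GT` (plus `FT`) fields.
#' Internal 0-based starts are converted to 1-based POS.
#'
#' @param sites Data frame with columns `chrom`, `start`, `end`, `svtype`,
#'   and optionally `filter` (default `PASS`) and `id`.
#' @param path Output path.
#' @param genotypes Optional site x sample character matrix of GT strings
#'   (e.g. `"0/1"`); column names are the sample IDs.
#' @param ft Optional site x sample matrix of per-genotype filter strings;
#'   requires `genotypes`.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_cnv_vcf <- function(sites, path, genotypes = NULL, ft = NULL,
                          contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Genotype filter\">"
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- !is.null(genotypes)
  if (has_gt) cols <- c(cols, "FORMAT", colnames(genotypes))
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  filt <- if (!is.null(sites$filter)) sites$filter else rep("PASS", nrow(sites))
  ids <- if (!is.null(sites$id)) sites$id else
    sprintf("cnv_%s_%d_%s", sites$chrom, sites$start + 1L, sites$svtype)
  body <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    fields <- c(sites$chrom[i], sites$start[i] + 1L, ids[i], "N",
                paste0("<", sites$svtype[i], ">"), ".", filt[i],
                sprintf("END=%d;SVTYPE=%s", sites$end[i], sites$svtype[i]))
    if (has_gt) {
      if (!is.null(ft)) {
        fields <- c(fields, "GT:FT", paste(genotypes[i, ], ft[i, ], sep = ":"))
      } else {
        fields <- c(fields, "GT", genotypes[i, ])
      }
    }
    body[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
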