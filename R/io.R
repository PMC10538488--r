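# Readers and writers for the on-disk formats: phased VCF / haplotype TSV,
# expression TSV, eQTL-map TSV, genetic-map TSV, and versioned JSON model
# bundles. Allele orientation is taken from the file (0 = REF, 1 = ALT) and
# never re-polarized; coordinates are 1-based as in VCF.

.BUNDLE_VERSION <- 1L

.readTSV <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.haplotypeColumnsToProfiles <- function(H, ids) {
  base <- sub("\\.[mp]$", "", ids)
  um <- unique(base)
  lapply(um, function(b) {
    mi <- match(paste0(b, ".m"), ids)
    pi <- match(paste0(b, ".p"), ids)
    if (is.na(mi) || is.na(pi))
      .stopf("sample '%s' lacks a complete .m/.p haplotype pair", b)
    GenotypeProfile(H[, mi], H[, pi], b)
  })
}

#' Read phased genotypes
#'
#' Reads either a phased VCF (GT fields like `0|1`; biallelic sites only) or
#' the package's plain haplotype TSV (columns `variant_id`, `position`, `cm`,
#' then one column per haplotype; profile haplotypes are named
#' `<sample>.m` / `<sample>.p`). Alleles are coded 0 = REF, 1 = ALT in file
#' orientation; site order is file order and must have strictly increasing
#' positions.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param as return a [HaplotypePanel-class] (`"panel"`), a list of
#'   [GenotypeProfile-class] (`"profiles"`), or decide from the column naming
#'   (`"auto"`: TSV with `.m`/`.p` pairs and every VCF load as profiles,
#'   otherwise a panel).
#' @param strict error on unphased or multiallelic records (default); when
#'   FALSE such records are skipped with a warning.
#' @param variantSubset optional variant identifiers to retain; an error is
#'   raised if any are missing from the file.
#' @param cmPerMb genetic-map fallback rate when the file carries no map
#'   (VCF input; default 1 cM/Mb).
#' @return a [HaplotypePanel-class] or list of [GenotypeProfile-class] with a
#'   `panel` attribute carrying the site metadata.
#' @export
readPhasedGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                                as = c("auto", "panel", "profiles"),
                                strict = TRUE, variantSubset = NULL,
                                cmPerMb = 1) {
  format <- match.arg(format)
  as <- match.arg(as)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    bi <- vcfR::is.biallelic(vcf)
    if (any(!bi)) {
      if (strict) .stopf("multiallelic record at %s:%s", fix[!bi, "CHROM"][1],
                         fix[!bi, "POS"][1])
      .warnf("skipping %d multiallelic record(s)", sum(!bi))
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    phased <- matrix(grepl("|", gt, fixed = TRUE), nrow(gt))
    bad <- !apply(phased, 1, all)
    if (any(bad & bi)) {
      off <- which(bad & bi)[1]
      if (strict) .stopf("unphased genotype at record %s:%s", fix[off, "CHROM"],
                         fix[off, "POS"])
      .warnf("skipping %d unphased record(s)", sum(bad & bi))
    }
    keep <- bi & !bad
    if (!any(keep)) .stopf("no usable phased biallelic records in '%s'", path)
    gt <- gt[keep, , drop = FALSE]
    ids <- fix[keep, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[noid]
    pos <- as.numeric(fix[keep, "POS"])
    hapM <- apply(gt, 2, function(col) as.integer(substr(col, 1, 1)))
    hapP <- apply(gt, 2, function(col) as.integer(substr(col, 3, 3)))
    H <- matrix(0L, length(pos), 2L * ncol(gt))
    H[, 2 * seq_len(ncol(gt)) - 1] <- hapM
    H[, 2 * seq_len(ncol(gt))] <- hapP
    colnames(H) <- as.vector(rbind(paste0(colnames(gt), ".m"),
                                   paste0(colnames(gt), ".p")))
    cm <- pos / 1e6 * cmPerMb
  } else {
    tab <- .readTSV(path)
    need <- c("variant_id", "position", "cm")
    if (!all(need %in% names(tab)))
      .stopf("haplotype TSV needs columns %s", paste(need, collapse = ", "))
    hapCols <- setdiff(names(tab), need)
    if (!length(hapCols)) .stopf("haplotype TSV has no haplotype columns")
    H <- as.matrix(tab[hapCols])
    storage.mode(H) <- "integer"
    ids <- as.character(tab$variant_id)
    pos <- as.numeric(tab$position)
    cm <- as.numeric(tab$cm)
  }
  if (!is.null(variantSubset)) {
    idx <- match(variantSubset, ids)
    if (anyNA(idx))
      .stopf("variant(s) missing from '%s': %s", path,
             paste(utils::head(variantSubset[is.na(idx)], 3), collapse = ", "))
    idx <- sort(idx)
    H <- H[idx, , drop = FALSE]; ids <- ids[idx]; pos <- pos[idx]; cm <- cm[idx]
  }
  if (is.unsorted(pos, strictly = TRUE))
    .stopf("positions in '%s' must be strictly increasing", path)
  isPair <- all(grepl("\\.[mp]$", colnames(H)))
  wantProfiles <- switch(as, profiles = TRUE, panel = FALSE,
                         auto = isPair || format == "vcf")
  if (wantProfiles) {
    if (!isPair) .stopf("cannot form diploid profiles: columns lack .m/.p pairs")
    out <- .haplotypeColumnsToProfiles(H, colnames(H))
    attr(out, "panel") <- HaplotypePanel(t(H), variantIds = ids, positions = pos,
                                         geneticPos = cm)
    out
  } else {
    HaplotypePanel(t(H), variantIds = ids, positions = pos, geneticPos = cm)
  }
}

#' Write phased genotypes
#'
#' Writes a [HaplotypePanel-class] or a list of [GenotypeProfile-class] to the
#' haplotype TSV dialect or to a minimal phased VCF (REF = A, ALT = G
#' placeholder alleles; chromosome "1"). TSV round-trips bit-exactly through
#' [readPhasedGenotypes()].
#'
#' @param x panel or profile list.
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @param panel site metadata when `x` is a profile list (falls back to 1 kb
#'   spacing when missing).
#' @return `path`, invisibly.
#' @export
writePhasedGenotypes <- function(x, path, format = c("tsv", "vcf"), panel = NULL) {
  format <- match.arg(format)
  if (is(x, "HaplotypePanel")) {
    H <- t(x@alleles)
    colnames(H) <- paste0("hap", seq_len(ncol(H)))
    ids <- x@variantIds; pos <- x@positions; cm <- x@geneticPos
  } else {
    x <- .asProfileList(x, "GenotypeProfile")
    H <- haplotypeMatrix(x)
    if (!is.null(panel)) {
      ids <- panel@variantIds; pos <- panel@positions; cm <- panel@geneticPos
    } else {
      ids <- paste0("v", seq_len(nrow(H))); pos <- seq_len(nrow(H)) * 1000
      cm <- pos / 1e6
    }
  }
  if (format == "tsv") {
    tab <- data.frame(variant_id = ids, position = pos, cm = cm,
                      check.names = FALSE)
    tab <- cbind(tab, as.data.frame(H, check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (ncol(H) %% 2L != 0L)
      .stopf("VCF output needs an even number of haplotypes (diploid samples)")
    samples <- unique(sub("\\.[mp]$", "", colnames(H)))
    if (length(samples) * 2L != ncol(H))
      samples <- paste0("s", seq_len(ncol(H) / 2L))
    gtcols <- vapply(seq_along(samples), function(i)
      paste0(H[, 2 * i - 1], "|", H[, 2 * i]), character(nrow(H)))
    gtcols <- matrix(gtcols, nrow = nrow(H))
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"))
    body <- apply(cbind("1", pos, ids, "A", "G", ".", "PASS", ".", "GT", gtcols),
                  1, paste, collapse = "\t")
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Read / write expression matrices
#'
#' The expression TSV has one `gene_id` column followed by one column per
#' sample; values must be numeric and gene identifiers unique.
#'
#' @param path file path.
#' @return `readExpression`: list of [ExpressionProfile-class].
#' @export
readExpression <- function(path) {
  tab <- .readTSV(path)
  if (names(tab)[1] != "gene_id") .stopf("expression TSV must start with gene_id")
  genes <- as.character(tab$gene_id)
  if (anyDuplicated(genes)) .stopf("duplicate gene identifiers in '%s'", path)
  M <- as.matrix(tab[-1])
  if (!is.numeric(M)) .stopf("non-numeric expression cells in '%s'", path)
  lapply(colnames(M), function(s) ExpressionProfile(M[, s], genes, s))
}

#' @param profiles list of [ExpressionProfile-class].
#' @rdname readExpression
#' @export
writeExpression <- function(profiles, path) {
  E <- expressionMatrix(.asProfileList(profiles, "ExpressionProfile"))
  tab <- data.frame(gene_id = rownames(E), E, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write eQTL maps
#'
#' The eQTL-map TSV has columns `variant_id`, `gene_id` and optionally
#' `direction` and `significance`, one row per eQTL-eGene association. Rows
#' sharing a variant are merged into one factor site (their eGene sets are
#' pooled; the maximum significance is kept). Variants absent from the panel
#' are dropped with a message reporting the retained count.
#'
#' @param path file path.
#' @param panel the [HaplotypePanel-class] the variant identifiers resolve
#'   against.
#' @return `readEQTLMap`: an [EQTLMap-class].
#' @export
readEQTLMap <- function(path, panel) {
  tab <- .readTSV(path)
  if (!all(c("variant_id", "gene_id") %in% names(tab)))
    .stopf("eQTL map TSV needs variant_id and gene_id columns")
  site <- match(tab$variant_id, panel@variantIds)
  drop <- is.na(site)
  if (any(drop))
    message(sprintf("eQTL map: %d of %d association(s) matched the genotype data",
                    sum(!drop), nrow(tab)))
  tab <- tab[!drop, , drop = FALSE]
  site <- site[!drop]
  if (!nrow(tab)) .stopf("no eQTL in '%s' overlaps the panel", path)
  ord <- order(site)
  tab <- tab[ord, , drop = FALSE]; site <- site[ord]
  bySite <- split(seq_len(nrow(tab)), site)
  sites <- as.integer(names(bySite))
  EQTLMap(siteIndex = sites,
          geneSets = lapply(bySite, function(i) unique(tab$gene_id[i])),
          variantIds = panel@variantIds[sites],
          direction = vapply(bySite, function(i) {
            if ("direction" %in% names(tab)) as.numeric(tab$direction[i][1]) else NA_real_
          }, 0),
          significance = vapply(bySite, function(i) {
            if ("significance" %in% names(tab)) max(as.numeric(tab$significance[i])) else NA_real_
          }, 0))
}

#' @param map an [EQTLMap-class].
#' @rdname readEQTLMap
#' @export
writeEQTLMap <- function(map, path) {
  rows <- do.call(rbind, lapply(seq_along(map@siteIndex), function(s)
    data.frame(variant_id = map@variantIds[s], gene_id = map@geneSets[[s]],
               direction = map@direction[s], significance = map@significance[s],
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map and apply it to a panel
#'
#' The genetic-map TSV has columns `variant_id` and `cm`. Variants of the
#' panel missing from the map, or a file without a `cm` column, fall back to a
#' uniform-rate map derived from physical positions (1 cM/Mb) with a warning.
#'
#' @param path file path.
#' @param panel a [HaplotypePanel-class].
#' @return numeric vector of genetic positions (cM) over the panel's sites.
#' @export
readGeneticMap <- function(path, panel) {
  tab <- .readTSV(path)
  if (!all(c("variant_id", "cm") %in% names(tab))) {
    .warnf("genetic map lacks variant_id/cm columns: uniform 1 cM/Mb fallback")
    return(panel@positions / 1e6)
  }
  cm <- as.numeric(tab$cm)[match(panel@variantIds, tab$variant_id)]
  if (anyNA(cm)) {
    .warnf("genetic map misses %d panel variant(s): uniform 1 cM/Mb fallback",
           sum(is.na(cm)))
    return(panel@positions / 1e6)
  }
  cm
}

#' Apply genetic-map coordinates to a panel
#'
#' @param panel a [HaplotypePanel-class].
#' @param cm numeric genetic positions, one per site.
#' @return the panel with `geneticPos` replaced.
#' @export
applyGeneticMap <- function(panel, cm) {
  HaplotypePanel(panel@alleles, variantIds = panel@variantIds,
                 positions = panel@positions, geneticPos = cm)
}

# ---- model bundles ----------------------------------------------------------

.mapToJSON <- function(map) {
  list(variant_id = map@variantIds, site_index = map@siteIndex,
       gene_sets = map@geneSets, direction = map@direction,
       significance = map@significance)
}

.mapFromJSON <- function(x) {
  EQTLMap(siteIndex = x$site_index, geneSets = x$gene_sets,
          variantIds = x$variant_id, direction = x$direction,
          significance = x$significance)
}

#' Map fingerprint
#'
#' Content hash of an eQTL map, recorded in model bundles and provenance so a
#' linking run can refuse a model trained against a different map.
#'
#' @param map an [EQTLMap-class].
#' @return hex string.
#' @export
eqtlMapHash <- function(map) {
  .contentHash(paste(map@variantIds, map@siteIndex,
                     vapply(map@geneSets, paste, "", collapse = ","),
                     sep = ":"))
}

#' Serialize / load trained models
#'
#' Writes a trained scorer ([DSMParams-class], [GNBParams-class] or
#' [EBLParams-class]) to a versioned JSON bundle including the eQTL map, its
#' hash, and all parameters; `readModelBundle` reconstructs the S4 object.
#'
#' @param params a trained scorer.
#' @param path output / input file.
#' @param sourceMapHash optional fingerprint of the full eQTL-map file the
#'   model was trained from (see [eqtlMapHash()]); for baselines whose map was
#'   pruned during fitting this records the pre-pruning map so that linking
#'   runs can verify provenance against the original file.
#' @return `readModelBundle`: the reconstructed parameter object.
#' @export
writeModelBundle <- function(params, path, sourceMapHash = NULL) {
  bundle <- c(list(format_version = .BUNDLE_VERSION), .modelToJSON(params))
  if (!is.null(sourceMapHash)) bundle$source_map_hash <- sourceMapHash
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.modelToJSON <- function(params) {
  if (is(params, "DSMParams")) {
    list(type = "dsm", map = .mapToJSON(params@map),
         map_hash = eqtlMapHash(params@map),
         alpha = params@qtl@alpha, beta = params@qtl@beta,
         expr_center = as.list(params@exprCenter),
         expr_scale = as.list(params@exprScale),
         hmm = list(switch_prob = params@hmm@switchProb,
                    emission_error = params@hmm@emissionError,
                    prior = params@hmm@prior),
         history = params@history)
  } else if (is(params, "GNBParams")) {
    list(type = "gnb", map = .mapToJSON(params@map),
         map_hash = eqtlMapHash(params@map),
         gene = params@gene, mu = params@mu, sigma = params@sigma,
         log_prior = params@logPrior)
  } else if (is(params, "EBLParams")) {
    list(type = "ebl", map_hash = eqtlMapHash(params@gnb@map),
         gnb = .modelToJSON(params@gnb),
         extremity_q = params@extremityQ, corr_min = params@corrMin,
         lambda = params@lambda, corr = params@corr, lo = params@lo,
         hi = params@hi)
  } else .stopf("unsupported model class '%s'", class(params)[1])
}

#' @rdname writeModelBundle
#' @export
readModelBundle <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                          simplifyDataFrame = FALSE)
  if (is.null(b$format_version) || b$format_version > .BUNDLE_VERSION)
    .stopf("unsupported bundle version in '%s'", path)
  .rebuildModel(b)
}

.rowsToMatrix <- function(rows, ncol) {
  matrix(unlist(rows, use.names = FALSE), ncol = ncol, byrow = TRUE)
}

.rebuildModel <- function(b) {
  if (b$type == "dsm") {
    beta <- b$beta
    if (!is.list(beta)) beta <- as.list(beta)
    new("DSMParams",
        hmm = HMMParams(as.numeric(b$hmm$switch_prob), b$hmm$emission_error,
                        as.numeric(b$hmm$prior)),
        qtl = new("QTLFactorParams", alpha = as.numeric(b$alpha),
                  beta = lapply(beta, as.numeric)),
        map = .mapFromJSON(b$map),
        exprCenter = unlist(b$expr_center), exprScale = unlist(b$expr_scale),
        history = as.numeric(b$history))
  } else if (b$type == "gnb") {
    new("GNBParams", map = .mapFromJSON(b$map), gene = as.character(b$gene),
        mu = .rowsToMatrix(b$mu, 3L), sigma = as.numeric(b$sigma),
        logPrior = .rowsToMatrix(b$log_prior, 3L))
  } else if (b$type == "ebl") {
    new("EBLParams", gnb = .rebuildModel(b$gnb),
        extremityQ = as.numeric(b$extremity_q),
        corrMin = as.numeric(b$corr_min), lambda = as.numeric(b$lambda),
        corr = as.numeric(b$corr), lo = as.numeric(b$lo), hi = as.numeric(b$hi))
  } else .stopf("unknown bundle type '%s'", b$type)
}
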