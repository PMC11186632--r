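## Clone-level BCR repertoire statistics: clone construction and filtering,
## Chao1 richness, clonal overlap, public-clone detection and enrichment,
## isotype composition, and somatic-hypermutation aggregation per IGHV
## allele with paired testing.

.isotypeFromCCall <- function(c_call) {
  up <- toupper(as.character(c_call))
  out <- rep("unknown", length(up))
  out[grepl("^IGHM|^IGM", up)] <- "IgM"
  out[grepl("^IGHD|^IGD", up)] <- "IgD"
  out[grepl("^IGHG|^IGG", up)] <- "IgG"
  out[grepl("^IGHE|^IGE", up)] <- "IgE"
  out[grepl("^IGHA|^IGA", up)] <- "IgA"
  out
}

#' Build a clone table from AIRR-style rearrangement rows
#'
#' Groups rows by clone key — V gene (allele suffix dropped) plus exact CDR3
#' amino-acid sequence — within the heavy-chain locus, sums duplicate counts
#' into clone sizes, and removes small clones (size below `min_size`, 10 by
#' default). Rows with a missing CDR3 or a non-IGH locus are dropped and
#' logged. Member sequences (ids, mutation counts, V lengths, full allele
#' calls) are retained per clone for downstream mutation analysis.
#'
#' @param rearrangements data.frame with columns `v_call`, `junction_aa`,
#'   `duplicate_count`, and optionally `locus`, `c_call`, `mutation_count`,
#'   `v_sequence_length`, `sequence_id`, `sample_id`.
#' @param min_size clone-size filter (default 10; use 1 to keep all clones).
#' @param metadata optional one-row data.frame with `sample_id`, `mouse_id`,
#'   `tissue`, `subset`, `timepoint_day`, `age_group`.
#' @return A [RepertoireSample-class].
#' @examples
#' rows <- data.frame(v_call = c("IGHV1-1*01", "IGHV1-1*02", "IGHV2-1*01"),
#'                    junction_aa = c("CARWAY", "CARWAY", "CGGF"),
#'                    duplicate_count = c(8, 4, 20), c_call = "IGHA")
#' nClones(buildClones(rows))  # the *01/*02 rows merge into one clone
#' @export
buildClones <- function(rearrangements, min_size = 10, metadata = NULL) {
  r <- as.data.frame(rearrangements)
  n0 <- nrow(r)
  if (is.null(r$v_call)) r$v_call <- rep(NA_character_, n0)
  if (is.null(r$junction_aa)) r$junction_aa <- rep(NA_character_, n0)
  if (is.null(r$locus)) r$locus <- rep("IGH", n0)
  if (is.null(r$duplicate_count)) r$duplicate_count <- rep(1, n0)
  if (is.null(r$c_call)) r$c_call <- rep(NA_character_, n0)
  if (is.null(r$mutation_count)) r$mutation_count <- rep(NA_real_, n0)
  if (is.null(r$v_sequence_length)) r$v_sequence_length <- rep(NA_real_, n0)
  if (is.null(r$sequence_id)) r$sequence_id <- sprintf("seq%05d", seq_len(n0))

  noCdr3 <- is.na(r$junction_aa) | !nzchar(as.character(r$junction_aa))
  r <- r[!noCdr3, , drop = FALSE]
  offLocus <- is.na(r$locus) | r$locus != "IGH"
  r <- r[!offLocus, , drop = FALSE]

  dropped <- c(missing_cdr3 = sum(noCdr3), non_igh = sum(offLocus),
               below_min_size = 0L)

  if (nrow(r)) {
    r$v_gene <- sub("\\*.*$", "", as.character(r$v_call))
    r$clone_key <- paste(r$v_gene, r$junction_aa, sep = "_")
    grp <- split(seq_len(nrow(r)), r$clone_key)
    clones <- do.call(rbind, lapply(grp, function(i) {
      sz <- sum(r$duplicate_count[i])
      iso <- .isotypeFromCCall(r$c_call[i])
      isoTot <- tapply(r$duplicate_count[i], iso, sum)
      data.frame(clone_key = r$clone_key[i[1L]], v_gene = r$v_gene[i[1L]],
                 junction_aa = as.character(r$junction_aa[i[1L]]),
                 isotype = names(isoTot)[which.max(isoTot)],
                 size = sz, n_seqs = length(i))
    }))
    clones$seq_ids <- lapply(grp, function(i) r$sequence_id[i])
    clones$seq_mutations <- lapply(grp, function(i) r$mutation_count[i])
    clones$seq_v_lengths <- lapply(grp, function(i) r$v_sequence_length[i])
    clones$seq_alleles <- lapply(grp, function(i) as.character(r$v_call[i]))
    small <- clones$size < min_size
    dropped[["below_min_size"]] <- sum(small)
    clones <- clones[!small, , drop = FALSE]
    clones <- clones[order(clones$clone_key), , drop = FALSE]
    rownames(clones) <- NULL
  } else {
    clones <- data.frame(clone_key = character(0), v_gene = character(0),
                         junction_aa = character(0), isotype = character(0),
                         size = numeric(0), n_seqs = integer(0))
    clones$seq_ids <- list()
    clones$seq_mutations <- list()
    clones$seq_v_lengths <- list()
    clones$seq_alleles <- list()
  }
  if (is.null(metadata)) {
    sid <- if (!is.null(rearrangements$sample_id) && n0 > 0)
      as.character(rearrangements$sample_id[1L]) else "sample1"
    metadata <- data.frame(sample_id = sid, mouse_id = sid,
                           tissue = NA_character_, subset = NA_character_,
                           timepoint_day = NA_real_, age_group = NA_character_)
  }
  new("RepertoireSample", sampleId = as.character(metadata$sample_id),
      mouseId = as.character(metadata$mouse_id),
      tissue = as.character(metadata$tissue),
      subset = as.character(metadata$subset),
      timepoint = as.numeric(metadata$timepoint_day),
      ageGroup = as.character(metadata$age_group),
      clones = clones, dropped = as.integer(dropped) |>
        stats::setNames(names(dropped)))
}

#' Expand a clone table back into rearrangement rows
#'
#' Inverse of [buildClones()] up to row order: one row per member sequence.
#' Useful for round trips and idempotence checks.
#'
#' @param sample a [RepertoireSample-class].
#' @return data.frame of AIRR-style rows.
#' @export
asRearrangements <- function(sample) {
  stopifnot(is(sample, "RepertoireSample"))
  cl <- sample@clones
  if (!nrow(cl))
    return(data.frame(sequence_id = character(0), sample_id = character(0),
                      locus = character(0), v_call = character(0),
                      c_call = character(0), junction_aa = character(0),
                      duplicate_count = numeric(0), mutation_count = numeric(0),
                      v_sequence_length = numeric(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    k <- cl$n_seqs[i]
    ## split the clone size over member sequences, first row takes remainder
    per <- rep(cl$size[i] %/% k, k)
    per[1L] <- per[1L] + cl$size[i] - sum(per)
    data.frame(sequence_id = unlist(cl$seq_ids[i]),
               sample_id = sample@sampleId, locus = "IGH",
               v_call = unlist(cl$seq_alleles[i]), c_call = cl$isotype[i],
               junction_aa = cl$junction_aa[i], duplicate_count = per,
               mutation_count = unlist(cl$seq_mutations[i]),
               v_sequence_length = unlist(cl$seq_v_lengths[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Chao1 richness estimate
#'
#' `S_obs + f1^2 / (2 f2)` when doubletons exist, and the bias-corrected
#' `S_obs + f1 (f1 - 1) / 2` when `f2 = 0`, where `f1` and `f2` count clones
#' of size exactly 1 and 2. Note that after the default size-10 clone filter
#' a repertoire has no singletons, so Chao1 equals the observed richness;
#' build clones with `min_size = 1` to estimate unseen richness.
#'
#' @param x a [RepertoireSample-class], or a numeric vector of clone sizes.
#' @return the richness estimate (numeric scalar).
#' @examples
#' chao1(c(1, 1, 1, 2, 2, 3))  # 6 + 9/4 = 8.25
#' @export
chao1 <- function(x) {
  sizes <- if (is(x, "RepertoireSample")) x@clones$size else as.numeric(x)
  if (!length(sizes)) .stopf("chao1: empty sample")
  S <- length(sizes)
  f1 <- sum(sizes == 1)
  f2 <- sum(sizes == 2)
  if (f2 > 0) S + f1^2 / (2 * f2) else S + f1 * (f1 - 1) / 2
}

#' Percentage of clones shared between two samples
#'
#' Shared clone keys as a percentage of, depending on `mode`: the union of
#' both key sets (`"jaccard"`, default), the first sample's key set
#' (`"first"`), or the smaller key set (`"min"`).
#'
#' @param a,b [RepertoireSample-class] objects (non-empty).
#' @param mode denominator convention.
#' @return percentage in \[0, 100\].
#' @export
overlapFraction <- function(a, b, mode = c("jaccard", "first", "min")) {
  stopifnot(is(a, "RepertoireSample"), is(b, "RepertoireSample"))
  mode <- match.arg(mode)
  ka <- a@clones$clone_key
  kb <- b@clones$clone_key
  if (!length(ka) || !length(kb)) .stopf("overlapFraction: empty sample")
  shared <- length(intersect(ka, kb))
  den <- switch(mode,
                jaccard = length(union(ka, kb)),
                first = length(ka),
                min = min(length(ka), length(kb)))
  100 * shared / den
}

#' Detect public clones across samples
#'
#' A clone is public when its key occurs in at least two samples belonging
#' to at least two distinct mice.
#'
#' @param samples list of [RepertoireSample-class] objects; every sample
#'   must carry a mouse id.
#' @return A [PublicCloneCatalog-class]; entries are ordered by total
#'   abundance (descending), ties broken by clone key.
#' @export
findPublicClones <- function(samples) {
  stopifnot(length(samples) > 0,
            all(vapply(samples, is, logical(1), "RepertoireSample")))
  occ <- do.call(rbind, lapply(samples, function(s) {
    cl <- s@clones
    if (!nrow(cl)) return(NULL)
    data.frame(clone_key = cl$clone_key, sample_id = s@sampleId,
               mouse_id = s@mouseId, subset = s@subset, size = cl$size)
  }))
  if (is.null(occ)) occ <- data.frame(clone_key = character(0),
                                      sample_id = character(0),
                                      mouse_id = character(0),
                                      subset = character(0), size = numeric(0))
  byKey <- split(occ, occ$clone_key)
  ent <- do.call(rbind, lapply(byKey, function(o) {
    data.frame(clone_key = o$clone_key[1L], n_samples = nrow(o),
               n_mice = length(unique(o$mouse_id)), total_size = sum(o$size))
  }))
  if (is.null(ent)) ent <- data.frame(clone_key = character(0),
                                      n_samples = integer(0),
                                      n_mice = integer(0),
                                      total_size = numeric(0))
  pub <- ent[ent$n_samples >= 2 & ent$n_mice >= 2, , drop = FALSE]
  pub <- pub[order(-pub$total_size, pub$clone_key), , drop = FALSE]
  rownames(pub) <- NULL
  occ <- occ[occ$clone_key %in% pub$clone_key, , drop = FALSE]
  occ <- occ[order(occ$clone_key, occ$sample_id), , drop = FALSE]
  rownames(occ) <- NULL
  new("PublicCloneCatalog", entries = pub, occurrences = occ)
}

#' Enrichment of top public clones in a target subset
#'
#' Ranks public clones by total abundance (ties broken by clone key), takes
#' the `n_top` most abundant, and reports the fraction occurring in at least
#' one sample of the target subset, together with the corresponding baseline
#' fraction over all clones of all samples.
#'
#' @param catalog a [PublicCloneCatalog-class] (non-empty).
#' @param samples the list of [RepertoireSample-class] objects the catalog
#'   was built from (for the baseline).
#' @param n_top number of top public clones (default 100).
#' @param target_subset subset label of interest (default `"llpc"`).
#' @return list with `topFraction`, `baselineFraction`, `nTopUsed`, and
#'   `topKeys`.
#' @export
topPublicEnrichment <- function(catalog, samples, n_top = 100,
                                target_subset = "llpc") {
  stopifnot(is(catalog, "PublicCloneCatalog"))
  if (!.isCount(n_top, min = 1L)) .stopf("n_top must be >= 1")
  if (!nrow(catalog@entries)) .stopf("topPublicEnrichment: empty catalog")
  ent <- catalog@entries  # already ranked by total_size then key
  top <- utils::head(ent$clone_key, n_top)
  occ <- catalog@occurrences
  inTarget <- unique(occ$clone_key[occ$subset == target_subset])
  allKeys <- unique(unlist(lapply(samples, function(s) s@clones$clone_key)))
  targetKeys <- unique(unlist(lapply(samples, function(s) {
    if (identical(s@subset, target_subset)) s@clones$clone_key else character(0)
  })))
  list(topFraction = mean(top %in% inTarget),
       baselineFraction = mean(allKeys %in% targetKeys),
       nTopUsed = length(top), topKeys = top)
}

#' Isotype composition of a sample
#'
#' Fractions of clones (default) or of reads (clone sizes) per isotype,
#' summing to one.
#'
#' @param sample a [RepertoireSample-class] (non-empty).
#' @param weight `"clones"` or `"reads"`.
#' @return named numeric vector over the isotypes present.
#' @export
isotypeComposition <- function(sample, weight = c("clones", "reads")) {
  stopifnot(is(sample, "RepertoireSample"))
  weight <- match.arg(weight)
  cl <- sample@clones
  if (!nrow(cl)) .stopf("isotypeComposition: empty sample")
  w <- if (weight == "clones") rep(1, nrow(cl)) else cl$size
  tot <- tapply(w, cl$isotype, sum)
  out <- as.numeric(tot) / sum(w)
  names(out) <- names(tot)
  out
}

#' Mean mutation frequency per IGHV allele
#'
#' Draws one representative sequence uniformly per clone (seeded, to avoid
#' double-counting mutations within a clone), computes its mutation
#' frequency (mutations / V-gene length), and averages the representatives'
#' frequencies per IGHV allele.
#'
#' @param sample a [RepertoireSample-class].
#' @param seed integer RNG seed (required).
#' @return data.frame with `v_allele`, `mean_freq`, `n_clones`.
#' @export
shmPerAllele <- function(sample, seed) {
  stopifnot(is(sample, "RepertoireSample"))
  cl <- sample@clones
  if (!nrow(cl)) .stopf("shmPerAllele: empty sample")
  reps <- withSeed(seed, vapply(cl$n_seqs, function(k) sample.int(k, 1L),
                                integer(1)))
  mut <- mapply(function(m, j) m[[j]], cl$seq_mutations, reps)
  len <- mapply(function(l, j) l[[j]], cl$seq_v_lengths, reps)
  allele <- mapply(function(a, j) a[[j]], cl$seq_alleles, reps)
  if (any(!is.finite(len)) || any(len <= 0))
    .stopf("shmPerAllele: non-positive or missing V length")
  freq <- mut / len
  out <- data.frame(v_allele = names(tapply(freq, allele, mean)),
                    mean_freq = as.numeric(tapply(freq, allele, mean)),
                    n_clones = as.integer(table(allele)[names(tapply(freq, allele, mean))]))
  out <- out[order(out$v_allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired t test on allele-matched mutation frequencies
#'
#' Matches the two per-allele tables on allele name (alleles present in only
#' one table are discarded) and performs a two-sided paired t test on the
#' matched frequency pairs.
#'
#' @param a,b data.frames from [shmPerAllele()].
#' @return list with `n_alleles`, `t`, `df`, `p`, `mean_diff`, and `flag`
#'   (`"ok"`, `"too_few_alleles"`, or `"zero_variance"`; no p is reported
#'   for degenerate cases).
#' @export
pairedAlleleTest <- function(a, b) {
  m <- intersect(a$v_allele, b$v_allele)
  if (length(m) < 2L)
    return(list(n_alleles = length(m), t = NA_real_, df = NA_real_,
                p = NA_real_, mean_diff = NA_real_, flag = "too_few_alleles"))
  xa <- a$mean_freq[match(m, a$v_allele)]
  xb <- b$mean_freq[match(m, b$v_allele)]
  dif <- xa - xb
  if (diff(range(dif)) <= 1e-12 * max(1, max(abs(dif)))) {
    if (all(dif == 0))   # identical vectors: no effect, t = 0, p = 1
      return(list(n_alleles = length(m), t = 0, df = length(m) - 1, p = 1,
                  mean_diff = 0, flag = "ok"))
    return(list(n_alleles = length(m), t = NA_real_, df = length(m) - 1,
                p = NA_real_, mean_diff = mean(dif), flag = "zero_variance"))
  }
  tt <- stats::t.test(xa, xb, paired = TRUE)
  list(n_alleles = length(m), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, mean_diff = mean(dif),
       flag = "ok")
}

#' Family of paired allele tests with BH correction
#'
#' Runs [pairedAlleleTest()] for every comparison in the family and adjusts
#' the resulting p-values across the family by the Benjamini-Hochberg
#' procedure.
#'
#' @param comparisons named list; each element is a list with components
#'   `a` and `b` (per-allele tables from [shmPerAllele()]).
#' @return data.frame with one row per comparison: `comparison`,
#'   `n_alleles`, `t`, `df`, `p`, `p_adj`, `flag`.
#' @export
pairedAlleleFamily <- function(comparisons) {
  stopifnot(length(comparisons) > 0)
  if (is.null(names(comparisons)))
    names(comparisons) <- sprintf("comparison%d", seq_along(comparisons))
  res <- lapply(comparisons, function(cmp) pairedAlleleTest(cmp$a, cmp$b))
  out <- data.frame(
    comparison = names(comparisons),
    n_alleles = vapply(res, function(r) as.integer(r$n_alleles), integer(1)),
    t = vapply(res, function(r) r$t, numeric(1)),
    df = vapply(res, function(r) as.numeric(r$df), numeric(1)),
    p = vapply(res, function(r) r$p, numeric(1)),
    flag = vapply(res, function(r) r$flag, character(1)))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("comparison", "n_alleles", "t", "df", "p", "p_adj", "flag")]
}
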