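#' Simulate a cohort with planted introgression
#'
#' Founder-mosaic forward model: founder haplotypes per population are
#' mutated copies of a shared ancestor (expected pairwise divergence
#' `2 * mu * t_split` between the ingroup populations, `2 * mu * t_og`
#' against the outgroup, `2 * mu * t_within * (1 - 1/K)` within a
#' population), each sample haplotype is a recombinant mosaic of its
#' population's founders, and the cultivar group carries a planted
#' admixture pulse (see [sim_config()]).  The emitted table holds the
#' polymorphic biallelic sites only, with QUAL/FS/MQ site annotations,
#' genotype-call errors at `error_rate` and a correctness-dependent GQ
#' model.  Ground truth — ancestry tracts, true IBD segments, the causal
#' region — is returned alongside.  A fixed seed reproduces the cohort
#' bit for bit.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_cohort`: `table` (a [variant_table()]),
#'   `truth` (list with `tracts`, `true_ibd`, `causal_region`,
#'   `causal_donor`, `causal_effect`), `populations` (named vector
#'   sample id -> population), `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  local_rng(cfg$seed)
  L <- cfg$seq_length
  K <- cfg$founders_per_pop
  pools <- list(OH = paste0("OH_f", seq_len(K)),
                ONL = paste0("ONL_f", seq_len(K)),
                OG = paste0("OG_f", seq_len(K)))
  founders <- unlist(pools, use.names = FALSE)

  # -- mutations on the founder genealogy (infinite sites) ----------------
  tw <- cfg$t_within
  branches <- list(
    list(len = cfg$t_og - tw[["OG"]], carriers = pools$OG),
    list(len = cfg$t_og - cfg$t_split, carriers = c(pools$OH, pools$ONL)),
    list(len = cfg$t_split - tw[["OH"]], carriers = pools$OH),
    list(len = cfg$t_split - tw[["ONL"]], carriers = pools$ONL))
  for (p in c("OH", "ONL", "OG"))
    for (fd in pools[[p]])
      branches[[length(branches) + 1L]] <-
        list(len = tw[[p]], carriers = fd)
  n_mut <- vapply(branches, function(b)
    stats::rpois(1L, cfg$mu * b$len * L), integer(1))
  # standing variation predating the split, shared by both ingroup pools
  # and absent from the outgroup (incomplete lineage sorting)
  n_anc <- stats::rpois(1L, cfg$anc_poly_factor * cfg$mu * cfg$t_split * L)
  total <- sum(n_mut) + n_anc
  pos <- sample.int(L, total)                  # distinct integer positions
  branch_of <- rep(c(seq_along(branches), 0L), c(n_mut, n_anc))
  ord <- order(pos)
  pos <- pos[ord]; branch_of <- branch_of[ord]

  A <- matrix(0L, nrow = total, ncol = length(founders),
              dimnames = list(NULL, founders))
  for (b in seq_along(branches))
    A[branch_of == b, branches[[b]]$carriers] <- 1L
  if (n_anc > 0L) {
    anc_rows <- which(branch_of == 0L)
    ingroup <- c(pools$OH, pools$ONL)
    q <- stats::runif(n_anc, 0.1, 0.9)
    A[anc_rows, ingroup] <-
      (matrix(stats::runif(n_anc * length(ingroup)), n_anc) < q) * 1L
  }

  # ref/alt with transition odds kappa : 1 against any transversion
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", C = "T", G = "A", T = "C")
  tv_partner <- rbind(A = c("C", "T"), C = c("A", "G"),
                      G = c("C", "T"), T = c("A", "G"))
  ref <- sample(bases, total, replace = TRUE)
  is_ts <- stats::runif(total) <
    cfg$transition_bias / (cfg$transition_bias + 1)
  alt <- unname(ts_partner[ref])
  which_tv <- sample(1:2, total, replace = TRUE)
  alt[!is_ts] <- tv_partner[cbind(match(ref[!is_ts], bases),
                                  which_tv[!is_ts])]

  # -- sample haplotypes as founder mosaics -------------------------------
  pops <- c(rep("OH", cfg$n_oh), rep("ONL", cfg$n_onl),
            rep("ONC", cfg$n_onc), rep("OG", cfg$n_og))
  ids <- paste0(pops, stats::ave(seq_along(pops), pops, FUN = seq_along))
  n_hap <- 2L * length(ids)
  bp_rate <- cfg$recomb_rate * L * cfg$admix_age

  template <- NULL
  if (cfg$admix_mode == "shared") {
    # One pulse into the cultivar group's common ancestor: donor tracts
    # are marked in random order until the donor share of the genome
    # reaches f exactly (the final tract is split at the boundary), so
    # the planted fraction is realized rather than left to high-variance
    # tract-count sampling.
    tb <- mosaic_breaks(L, bp_rate)
    iv <- data.frame(start = tb[-length(tb)], end = tb[-1L],
                     donor = "ONL")
    remaining <- round(cfg$admix_fraction * L)
    for (j in sample.int(nrow(iv))) {
      if (remaining <= 0) break
      len <- iv$end[j] - iv$start[j]
      if (len <= remaining) {
        iv$donor[j] <- "OH"
        remaining <- remaining - len
      } else {
        cut <- iv$start[j] + remaining
        iv <- rbind(iv,
                    data.frame(start = iv$start[j], end = cut,
                               donor = "OH"),
                    data.frame(start = cut, end = iv$end[j],
                               donor = "ONL"))
        iv <- iv[-j, ]
        remaining <- 0
      }
    }
    iv <- iv[order(iv$start), ]
    template <- list(edges = c(iv$start, L), donor = iv$donor)
  }

  H <- matrix(0L, nrow = total, ncol = n_hap)
  tracts <- vector("list", n_hap)
  for (i in seq_along(ids)) {
    for (h in 1:2) {
      col <- 2L * (i - 1L) + h
      tr <- one_haplotype_tracts(pops[i], cfg, pools, template, bp_rate, L)
      tr$sample_id <- ids[i]; tr$hap <- h
      tracts[[col]] <- tr
      fidx <- match(tr$founder_id, founders)
      site_tract <- findInterval(pos - 1L, tr$start)
      H[, col] <- A[cbind(seq_len(total), fidx[site_tract])]
    }
  }
  tracts <- do.call(rbind, tracts)
  tracts$chrom <- cfg$chrom
  tracts <- tracts[, c("sample_id", "hap", "chrom", "start", "end",
                       "donor_pop", "founder_id")]

  # -- keep polymorphic sites only ----------------------------------------
  ac <- rowSums(H)
  poly <- ac > 0L & ac < n_hap
  pos <- pos[poly]; ref <- ref[poly]; alt <- alt[poly]
  H <- H[poly, , drop = FALSE]
  S <- sum(poly)

  geno <- H[, seq(1L, n_hap, 2L), drop = FALSE] +
    H[, seq(2L, n_hap, 2L), drop = FALSE]
  colnames(geno) <- ids

  # -- genotype-call errors and GQ ----------------------------------------
  err <- matrix(stats::runif(S * length(ids)) < cfg$error_rate, S)
  if (any(err)) {
    geno[err] <- (geno[err] + sample(1:2, sum(err), replace = TRUE)) %% 3L
    # re-phase corrupted calls so haplotypes stay consistent
    idx <- which(err, arr.ind = TRUE)
    h1 <- ifelse(geno[err] == 2L, 1L, ifelse(geno[err] == 0L, 0L,
                                             stats::rbinom(sum(err), 1L, 0.5)))
    h2 <- geno[err] - h1
    H[cbind(idx[, 1L], 2L * idx[, 2L] - 1L)] <- h1
    H[cbind(idx[, 1L], 2L * idx[, 2L])] <- h2
  }
  gq <- matrix(0L, S, length(ids))
  gq[!err] <- 30L + stats::rpois(sum(!err), cfg$gq_correct_lambda)
  gq[err] <- stats::rpois(sum(err), cfg$gq_error_lambda)
  gq <- pmin(gq, 99L)

  # -- site annotations ----------------------------------------------------
  qual <- 60 + stats::rgamma(S, shape = 2, scale = 150)
  fs <- stats::rexp(S, rate = 1 / 5)
  mq <- stats::rnorm(S, 55, 3)
  bad <- stats::runif(S) < cfg$bad_site_frac
  if (any(bad)) {
    which_bad <- sample(c("qual", "fs", "mq"), sum(bad), replace = TRUE)
    jb <- which(bad)
    qual[jb[which_bad == "qual"]] <-
      stats::runif(sum(which_bad == "qual"), 2, 29.9)
    fs[jb[which_bad == "fs"]] <-
      60.1 + stats::rexp(sum(which_bad == "fs"), 1 / 20)
    mq[jb[which_bad == "mq"]] <-
      stats::runif(sum(which_bad == "mq"), 20, 39.9)
  }
  qual <- round(qual, 1); fs <- round(fs, 2); mq <- round(mq, 2)

  tab <- variant_table(chrom = rep(cfg$chrom, S), pos = pos,
                       ref = ref, alt = alt, geno = geno,
                       sample_ids = ids, qual = qual, fs = fs, mq = mq,
                       gq = gq, hap = H)

  truth <- list(tracts = tracts,
                true_ibd = derive_true_ibd(list(tracts = tracts),
                                           cfg$min_ibd_length),
                causal_region = pick_causal_region(cfg, template),
                causal_donor = "OH",
                causal_effect = cfg$causal_effect)
  structure(list(table = tab, truth = truth,
                 populations = stats::setNames(pops, ids),
                 config = cfg),
            class = "sim_cohort")
}

mosaic_breaks <- function(L, bp_rate) {
  k <- stats::rpois(1L, bp_rate)
  sort(unique(c(0, floor(stats::runif(k, 0, L)), L)))
}

# Ancestry tracts for one haplotype: its own crossover mosaic, with the
# donor pool fixed by the shared template for ONC (shared mode).
one_haplotype_tracts <- function(pop, cfg, pools, template, bp_rate, L) {
  own <- mosaic_breaks(L, bp_rate)
  if (pop != "ONC") {
    founder <- sample(pools[[pop]], length(own) - 1L, replace = TRUE)
    d <- data.frame(start = own[-length(own)], end = own[-1L],
                    donor_pop = pop, founder_id = founder,
                    stringsAsFactors = FALSE)
    return(merge_equal_tracts(d))
  }
  if (cfg$admix_mode == "independent") {
    donor <- ifelse(stats::runif(length(own) - 1L) < cfg$admix_fraction,
                    "OH", "ONL")
    founder <- vapply(donor, function(dp) sample(pools[[dp]], 1L),
                      character(1))
    d <- data.frame(start = own[-length(own)], end = own[-1L],
                    donor_pop = donor, founder_id = founder,
                    stringsAsFactors = FALSE)
    return(merge_equal_tracts(d))
  }
  edges <- sort(unique(c(own, template$edges)))
  lo <- edges[-length(edges)]; hi <- edges[-1L]
  own_tract <- findInterval(lo, own)
  donor <- template$donor[findInterval(lo, template$edges)]
  key <- paste(own_tract, donor)
  founder_for <- vapply(unique(key), function(k) {
    dp <- sub("^\\S+ ", "", k)
    sample(pools[[dp]], 1L)
  }, character(1))
  d <- data.frame(start = lo, end = hi, donor_pop = donor,
                  founder_id = unname(founder_for[key]),
                  stringsAsFactors = FALSE)
  merge_equal_tracts(d)
}

merge_equal_tracts <- function(d) {
  if (nrow(d) < 2L) return(d)
  new_run <- c(TRUE, d$founder_id[-1L] != d$founder_id[-nrow(d)])
  grp <- cumsum(new_run)
  data.frame(start = tapply(d$start, grp, min),
             end = tapply(d$end, grp, max),
             donor_pop = d$donor_pop[new_run],
             founder_id = d$founder_id[new_run],
             row.names = NULL, stringsAsFactors = FALSE)
}

pick_causal_region <- function(cfg, template) {
  span <- cfg$causal_region_bp
  mid <- floor(cfg$seq_length / 2)
  if (!is.null(template)) {
    w <- which(template$donor == "OH")
    if (length(w)) {
      lens <- template$edges[w + 1L] - template$edges[w]
      best <- w[which.max(lens)]
      mid <- floor((template$edges[best] + template$edges[best + 1L]) / 2)
    }
  }
  lo <- max(0, mid - span %/% 2)
  genomic_intervals(cfg$chrom, lo, min(cfg$seq_length, lo + span))
}

#' True IBD segments from ancestry tracts
#'
#' Two haplotypes are identical by descent wherever they copy the same
#' founder; this emits one segment per maximal same-founder overlap of at
#' least `min_length` bp, with `lod` set to the segment length in kb — a
#' drop-in stand-in for detector output, with perfect sensitivity.
#'
#' @param truth a truth set (or any list) with element `tracts`.
#' @param min_length minimum segment length in bp.
#' @return an `ibd_segments` data.frame (0-based half-open coordinates).
#' @export
derive_true_ibd <- function(truth, min_length = 1e5) {
  tr <- truth$tracts
  out <- list()
  for (fd in unique(tr$founder_id)) {
    sub <- tr[tr$founder_id == fd, , drop = FALSE]
    if (nrow(sub) < 2L) next
    gr <- IRanges::IRanges(start = sub$start + 1, end = sub$end)
    hits <- IRanges::findOverlaps(gr, gr,
                                  minoverlap = max(1, min_length))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    keep <- q < s &
      paste(sub$sample_id[q], sub$hap[q]) !=
        paste(sub$sample_id[s], sub$hap[s])
    q <- q[keep]; s <- s[keep]
    if (!length(q)) next
    # canonical endpoint order so per-pair merging sees one key
    flip <- paste(sub$sample_id[q], sub$hap[q]) >
      paste(sub$sample_id[s], sub$hap[s])
    qa <- ifelse(flip, s, q); sb <- ifelse(flip, q, s)
    st <- pmax(sub$start[qa], sub$start[sb])
    en <- pmin(sub$end[qa], sub$end[sb])
    out[[length(out) + 1L]] <- data.frame(
      sample_a = sub$sample_id[qa], hap_a = sub$hap[qa],
      sample_b = sub$sample_id[sb], hap_b = sub$hap[sb],
      chrom = sub$chrom[qa], start = st, end = en,
      lod = (en - st) / 1000, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    res <- data.frame(sample_a = character(), hap_a = integer(),
                      sample_b = character(), hap_b = integer(),
                      chrom = character(), start = numeric(),
                      end = numeric(), lod = numeric())
  } else {
    res <- do.call(rbind, out)
    res <- merge_adjacent_ibd(res)
    res <- res[res$end - res$start >= min_length, , drop = FALSE]
    res <- res[order(res$sample_a, res$hap_a, res$sample_b, res$hap_b,
                     res$start), ]
    rownames(res) <- NULL
  }
  class(res) <- c("ibd_segments", "data.frame")
  res
}

# A haplotype can copy the same founder over consecutive tracts of its
# partner's tiling; fuse book-ended/overlapping per-pair segments.
merge_adjacent_ibd <- function(d) {
  key <- paste(d$sample_a, d$hap_a, d$sample_b, d$hap_b, d$chrom)
  parts <- lapply(split(seq_len(nrow(d)), key), function(j) {
    s <- d[j, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    m <- IRanges::reduce(IRanges::IRanges(s$start + 1, s$end))
    data.frame(sample_a = s$sample_a[1L], hap_a = s$hap_a[1L],
               sample_b = s$sample_b[1L], hap_b = s$hap_b[1L],
               chrom = s$chrom[1L],
               start = IRanges::start(m) - 1, end = IRanges::end(m),
               lod = (IRanges::width(m)) / 1000,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Simulate phenotypes with a planted haplotype effect
#'
#' `phenotype = baseline + causal_effect * copies + N(0, noise_sd)`, where
#' `copies` counts the sample's haplotypes whose ancestry at the causal
#' region midpoint comes from the causal donor pool.
#'
#' @param tab the cohort's [variant_table()].
#' @param truth the cohort truth set (see [simulate_cohort()]).
#' @param noise_sd residual standard deviation in trait units.
#' @param seed RNG seed (phenotype noise only).
#' @param baseline trait baseline (default 100).
#' @param trait trait name for the output table.
#' @return a data.frame `sample_id`, `trait`, `value`, `causal_copies`.
#' @export
simulate_phenotypes <- function(tab, truth, noise_sd, seed = 1,
                                baseline = 100, trait = "yield") {
  reg <- truth$causal_region
  in_reg <- tab$chrom == reg$chrom & tab$pos > reg$start &
    tab$pos <= reg$end
  g <- tab$geno[in_reg, , drop = FALSE]
  if (!nrow(g) ||
      all(apply(g, 1L, function(r) length(unique(r[!is.na(r)])) <= 1L)))
    stop("causal region is monomorphic in the table; re-simulate ",
         "with a different seed or larger admix_fraction")
  local_rng(seed)
  tr <- truth$tracts
  mid <- (reg$start + reg$end) / 2
  at_mid <- tr[tr$start <= mid & tr$end > mid, , drop = FALSE]
  carrier <- at_mid$donor_pop == truth$causal_donor
  copies <- tapply(carrier, at_mid$sample_id, sum)
  samples <- tab$sample_ids
  cp <- as.integer(copies[samples])
  cp[is.na(cp)] <- 0L
  data.frame(sample_id = samples, trait = trait,
             value = baseline + truth$causal_effect * cp +
               stats::rnorm(length(samples), 0, noise_sd),
             causal_copies = cp, stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf`, `truth_tracts.tsv`, `true_ibd.tsv`, `samples.tsv`
#' and (when supplied) `phenotypes.tsv` under `dir`.
#'
#' @param cohort a `sim_cohort` (see [simulate_cohort()]).
#' @param dir output directory, created if needed.
#' @param phenotypes optional phenotype table from
#'   [simulate_phenotypes()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, phenotypes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$table, file.path(dir, "cohort.vcf"))
  utils::write.table(cohort$truth$tracts,
                     file.path(dir, "truth_tracts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ibd_segments(cohort$truth$true_ibd, file.path(dir, "true_ibd.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$populations),
               population = unname(cohort$populations)),
    file.path(dir, "samples.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(phenotypes))
    utils::write.table(phenotypes, file.path(dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
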