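# Synthetic data with planted ground truth: genomes carrying miRNA hairpin
# loci and contaminant repeats, per-tissue small-RNA libraries, a
# block-structured mRNA expression matrix, and promoter sets with planted
# PWM sites.  Every generator is deterministic given its seed; truth tables
# double as the acceptance oracle downstream.

DEFAULT_TISSUES <- c("SPN", "BRN", "KID", "HRT", "SKM", "HEO", "SEO", "MEO")

# Relative per-tissue expression templates for planted miRNA categories on
# the standard 8-tissue panel.  "eo" mimics electro-miRs (strongly
# EO-enriched), "muscle" the shared myomiR block (muscle + EO), and
# "muscle_only" muscle-restricted myomiRs that are depleted in electric
# organ; novel loci default to "eo" since species-specific miRNAs tend to
# be tissue-restricted.
PROFILE_TEMPLATES <- list(
  neural      = c(SPN = 5,   BRN = 5,   KID = 0.2, HRT = 0.2, SKM = 0.2,
                  HEO = 0.2, SEO = 0.2, MEO = 0.2),
  muscle      = c(SPN = 0.2, BRN = 0.2, KID = 0.5, HRT = 4,   SKM = 5,
                  HEO = 4,   SEO = 4,   MEO = 4),
  muscle_only = c(SPN = 0.2, BRN = 0.2, KID = 0.3, HRT = 1,   SKM = 5,
                  HEO = 0.3, SEO = 0.3, MEO = 0.3),
  eo          = c(SPN = 0.1, BRN = 0.1, KID = 0.2, HRT = 0.3, SKM = 0.5,
                  HEO = 5,   SEO = 5,   MEO = 5),
  kidney      = c(SPN = 0.3, BRN = 0.3, KID = 5,   HRT = 0.5, SKM = 0.3,
                  HEO = 0.3, SEO = 0.3, MEO = 0.3),
  ubiquitous  = c(SPN = 1,   BRN = 1,   KID = 1,   HRT = 1,   SKM = 1,
                  HEO = 1,   SEO = 1,   MEO = 1))

#' Configuration for the small-RNA simulation
#'
#' Bundles every tunable of the genome/library generators.  Defaults
#' describe the reference study conditions: an 8-tissue panel (spinal
#' cord, brain, kidney, heart, skeletal muscle and three electric organs),
#' 10 conserved plus 3 novel hairpin loci in 2 x 50 kb contigs, 10,000
#' reads per tissue, 0.5% per-base substitution error, and 3' non-template
#' A/U additions on 10% of miRNA reads.
#'
#' @param seed root seed; each generator derives an independent stream.
#' @param n_contigs,contig_len genome shape.
#' @param n_conserved,n_novel planted conserved / novel hairpin counts.
#' @param n_contaminants contaminant families (rRNA/snoRNA-like), placed
#'   both in the genome and in the contaminant database.
#' @param tissues ordered tissue labels.
#' @param depth reads per tissue (scalar or named by tissue).
#' @param error_rate per-base substitution probability.
#' @param nta_prob probability a miRNA read carries 1-2 non-template 3'
#'   A/U additions.
#' @param adapter 3' adapter ligated to every read.
#' @param mirna_fraction fraction of each library drawn from planted arms.
#' @param contaminant_fraction fraction drawn from contaminant families.
#' @param arm_bias fraction of a locus' expression on its dominant arm.
#' @param read_len raw read length before trimming.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_contigs = 2L, contig_len = 50000L,
                       n_conserved = 10L, n_novel = 3L,
                       n_contaminants = 5L, tissues = DEFAULT_TISSUES,
                       depth = 10000L, error_rate = 0.005,
                       nta_prob = 0.1,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       mirna_fraction = 0.7,
                       contaminant_fraction = 0.15, arm_bias = 0.8,
                       read_len = 50L) {
  if (length(depth) == 1L) depth <- setNames(rep(depth, length(tissues)),
                                             tissues)
  stopifnot(all(tissues %in% names(depth)),
            mirna_fraction + contaminant_fraction < 1,
            error_rate >= 0, error_rate < 1, nta_prob >= 0, nta_prob <= 1)
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_len = as.integer(contig_len),
                 n_conserved = as.integer(n_conserved),
                 n_novel = as.integer(n_novel),
                 n_contaminants = as.integer(n_contaminants),
                 tissues = tissues, depth = depth[tissues],
                 error_rate = error_rate, nta_prob = nta_prob,
                 adapter = adapter, mirna_fraction = mirna_fraction,
                 contaminant_fraction = contaminant_fraction,
                 arm_bias = arm_bias, read_len = as.integer(read_len)),
            class = "sim_config")
}

# pick a free placement interval on the contigs, with margin, bounded retries
place_interval <- function(len, contig_lens, occupied, margin = 300L,
                           retries = 200L) {
  for (i in seq_len(retries)) {
    ctg <- sample(names(contig_lens), 1L,
                  prob = as.numeric(contig_lens) / sum(contig_lens))
    maxstart <- contig_lens[[ctg]] - len - margin
    if (maxstart < margin + 1L) next
    start <- sample.int(maxstart - margin, 1L) + margin
    iv <- c(start - margin, start + len - 1L + margin)
    occ <- occupied[[ctg]]
    clash <- FALSE
    if (length(occ))
      for (o in occ) if (iv[1] <= o[2] && o[1] <= iv[2]) { clash <- TRUE; break }
    if (!clash) return(list(contig = ctg, start = start))
  }
  stop("could not place a planted element; contigs too small for the ",
       "requested loci (increase contig_len or reduce counts)")
}

# per-locus per-tissue expected expression fractions
make_profiles <- function(truth_cat, tissues, mirna_fraction) {
  n <- length(truth_cat)
  if (all(tissues %in% names(PROFILE_TEMPLATES[[1]]))) {
    prof <- t(vapply(truth_cat, function(cat)
      PROFILE_TEMPLATES[[cat]][tissues], numeric(length(tissues))))
  } else {
    # non-standard panel: one or two random home tissues per locus
    prof <- t(vapply(seq_len(n), function(i) {
      v <- rep(0.3, length(tissues))
      v[sample(length(tissues), sample(1:2, 1))] <- 5
      v
    }, numeric(length(tissues))))
  }
  prof <- prof * exp(matrix(rnorm(n * length(tissues), 0, 0.2), n))
  # scale every tissue so planted arms take up mirna_fraction of the library
  prof <- sweep(prof, 2L, colSums(prof) / mirna_fraction, "/")
  dimnames(prof) <- list(NULL, tissues)
  prof
}

#' Simulate a genome with planted miRNA hairpins and contaminants
#'
#' Builds random contigs and plants (i) conserved hairpin loci whose
#' dominant mature arm is drawn from an emitted conserved-miRNA catalog,
#' (ii) novel hairpin loci whose mature arm is at least 4 mismatches from
#' every catalog entry, and (iii) contaminant families written both into
#' the genome and into a separate contaminant database.  Each hairpin is
#' mature arm + loop (4-15 nt) + near-complementary star arm (reverse
#' complement with 1-3 substitutions), so the planted precursor folds into
#' a stem-loop recoverable by the discovery pipeline.
#'
#' @param config a [sim_config()].
#' @return a `mirna_sim` list: `genome` (named contigs), `catalog`
#'   (data frame `sequence`, `family`, `source`), `contaminants`,
#'   `config`, and `truth` with elements `loci` (placements + arms) and
#'   `profiles` (loci x tissues expected library fractions).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    # conserved catalog, with spare entries that stay unexpressed
    n_cat <- config$n_conserved + 5L
    cat_len <- sample(20:23, n_cat, replace = TRUE)
    catalog <- data.frame(
      sequence = vapply(cat_len, function(l) random_dna(1, l), character(1)),
      family = sprintf("mir-%d", 100L + seq_len(n_cat)),
      source = "synthetic-catalog", stringsAsFactors = FALSE)

    # novel matures: >= 4 mismatches from every catalog entry
    novel_seq <- character(config$n_novel)
    for (i in seq_len(config$n_novel)) {
      repeat {
        s <- random_dna(1, sample(20:23, 1))
        if (is.na(match_conserved(s, catalog, max_mismatch = 3L))) break
      }
      novel_seq[i] <- s
    }

    n_loci <- config$n_conserved + config$n_novel
    is_novel <- c(rep(FALSE, config$n_conserved), rep(TRUE, config$n_novel))
    mature <- c(catalog$sequence[seq_len(config$n_conserved)], novel_seq)
    family <- c(catalog$family[seq_len(config$n_conserved)],
                rep(NA_character_, config$n_novel))

    # category assignment drives expression profiles.  Most conserved
    # miRNAs are shared between electric organ and muscle or broadly
    # expressed (electrocytes being myogenic, EO/muscle-differential
    # miRNAs are a small minority); novel loci are EO-restricted
    # electro-miRs.
    cats <- c("muscle", "ubiquitous", "neural", "muscle", "kidney", "eo",
              "muscle", "ubiquitous", "muscle_only", "neural")
    category <- c(rep(cats, length.out = config$n_conserved),
                  rep("eo", config$n_novel))

    contigs <- setNames(random_dna(config$n_contigs, config$contig_len),
                        sprintf("contig%d", seq_len(config$n_contigs)))
    contig_lens <- setNames(rep(config$contig_len, config$n_contigs),
                            names(contigs))
    occupied <- setNames(vector("list", config$n_contigs), names(contigs))

    loci <- list()
    for (i in seq_len(n_loci)) {
      dominant <- sample(c("5p", "3p"), 1L, prob = c(0.7, 0.3))
      # 1-2 substitutions: more leaves too little duplex in a 20-23-nt
      # arm for the mature to stay >= 75% paired under an MFE fold
      star <- mutate_seq(revcomp(mature[i]), sample(1:2, 1L))
      loop <- random_dna(1, sample(4:15, 1L))
      if (dominant == "5p") {
        arm5 <- mature[i]; arm3 <- star
      } else {
        arm5 <- star; arm3 <- mature[i]
      }
      precursor <- paste0(arm5, loop, arm3)
      pl <- place_interval(nchar(precursor), contig_lens, occupied)
      occupied[[pl$contig]] <- c(occupied[[pl$contig]],
                                 list(c(pl$start,
                                        pl$start + nchar(precursor) - 1L)))
      substr(contigs[[pl$contig]], pl$start,
             pl$start + nchar(precursor) - 1L) <- precursor
      loci[[i]] <- data.frame(
        locus_id = if (is_novel[i]) sprintf("novel-%d",
                                            i - config$n_conserved)
                   else family[i],
        family = family[i], contig = pl$contig, start = pl$start,
        end = pl$start + nchar(precursor) - 1L, strand = "+",
        arm5_seq = arm5, arm5_start = 1L, arm3_seq = arm3,
        arm3_start = nchar(arm5) + nchar(loop) + 1L,
        dominant_arm = dominant, novel = is_novel[i],
        category = category[i], stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, loci)

    contam <- setNames(
      vapply(sample(100:300, config$n_contaminants, replace = TRUE),
             function(l) random_dna(1, l), character(1)),
      sprintf("contaminant%d", seq_len(config$n_contaminants)))
    contam_pl <- list()
    for (i in seq_along(contam)) {
      pl <- place_interval(nchar(contam[i]), contig_lens, occupied)
      occupied[[pl$contig]] <- c(occupied[[pl$contig]],
                                 list(c(pl$start,
                                        pl$start + nchar(contam[i]) - 1L)))
      substr(contigs[[pl$contig]], pl$start,
             pl$start + nchar(contam[i]) - 1L) <- contam[i]
      contam_pl[[i]] <- data.frame(
        name = names(contam)[i], contig = pl$contig, start = pl$start,
        end = pl$start + nchar(contam[i]) - 1L, stringsAsFactors = FALSE)
    }
    contam_pl <- do.call(rbind, contam_pl)

    profiles <- make_profiles(loci$category, config$tissues,
                              config$mirna_fraction)
    rownames(profiles) <- loci$locus_id

    structure(list(genome = contigs, catalog = catalog,
                   contaminants = contam, config = config,
                   truth = list(loci = loci, profiles = profiles,
                                contaminant_placements = contam_pl)),
              class = "mirna_sim")
  })
}

#' @export
print.mirna_sim <- function(x, ...) {
  cat(sprintf(paste0("mirna_sim: %d contigs (%s bp), %d conserved + %d ",
                     "novel loci, %d contaminant families, %d tissues\n"),
              length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ","),
              sum(!x$truth$loci$novel), sum(x$truth$loci$novel),
              length(x$contaminants), length(x$config$tissues)))
  invisible(x)
}

# expected per-arm library fractions (arms x tissues)
arm_fractions <- function(sim) {
  loci <- sim$truth$loci
  bias <- sim$config$arm_bias
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    share <- c("5p" = if (loci$dominant_arm[i] == "5p") bias else 1 - bias,
               "3p" = if (loci$dominant_arm[i] == "3p") bias else 1 - bias)
    for (arm in c("5p", "3p"))
      rows[[length(rows) + 1L]] <- sim$truth$profiles[i, ] * share[[arm]]
  }
  m <- do.call(rbind, rows)
  rownames(m) <- as.vector(t(outer(loci$locus_id, c("5p", "3p"), paste,
                                   sep = "-")))
  m
}

#' Simulate per-tissue small-RNA sequencing libraries
#'
#' Draws each tissue's reads from a multinomial over planted arm sequences
#' (expected fractions from the truth profiles), contaminant fragments,
#' and random junk.  miRNA reads optionally carry 1-2 non-template 3' A/U
#' additions, every read is extended with the adapter (plus downstream
#' primer sequence) to `read_len`, and per-base substitution errors are
#' applied at `error_rate`.  Realized (pre-error) per-arm draw counts are
#' recorded as the quantification truth.
#'
#' @param sim a `mirna_sim` from [simulate_genome()].
#' @param out_dir if non-NULL, write one FASTQ per tissue here.
#' @return list with `reads` (tissue -> character vector), `realized`
#'   (arms x tissues matrix of drawn read counts), `files` (FASTQ paths or
#'   NULL).
#' @export
simulate_small_rna_libraries <- function(sim, out_dir = NULL) {
  stopifnot(inherits(sim, "mirna_sim"))
  cfg <- sim$config
  if (!all(cfg$tissues %in% colnames(sim$truth$profiles)))
    stop("tissue label(s) absent from expression profiles")
  with_seed(derive_seed(cfg$seed, 2L), {
    af <- arm_fractions(sim)
    arms <- arm_table(sim$truth$loci)
    stopifnot(identical(rownames(af), arms$arm_id))
    tail_seq <- paste0(cfg$adapter, "ATCTCGTATGCCGTCTTCTGCTTGAAAA")
    reads <- list()
    realized <- matrix(0L, nrow = nrow(af), ncol = length(cfg$tissues),
                       dimnames = list(rownames(af), cfg$tissues))
    for (tis in cfg$tissues) {
      depth <- cfg$depth[[tis]]
      p_arm <- af[, tis]
      p <- c(p_arm, contaminant = cfg$contaminant_fraction,
             junk = max(0, 1 - sum(p_arm) - cfg$contaminant_fraction))
      counts <- as.integer(rmultinom(1L, depth, p))
      n_arm <- length(p_arm)
      realized[, tis] <- counts[seq_len(n_arm)]
      inserts <- rep(arms$sequence, counts[seq_len(n_arm)])

      # non-template 3' additions (A or U only, 1-2 nt)
      if (cfg$nta_prob > 0 && length(inserts)) {
        nta <- runif(length(inserts)) < cfg$nta_prob
        if (any(nta)) {
          nn <- sum(nta)
          k <- sample(1:2, nn, replace = TRUE)
          b1 <- sample(c("A", "T"), nn, replace = TRUE)
          b2 <- sample(c("A", "T"), nn, replace = TRUE)
          inserts[nta] <- paste0(inserts[nta], b1,
                                 ifelse(k == 2L, b2, ""))
        }
      }

      n_cont <- counts[n_arm + 1L]
      if (n_cont > 0) {
        fam <- sample(length(sim$contaminants), n_cont, replace = TRUE)
        wl <- sample(20:23, n_cont, replace = TRUE)
        st <- vapply(seq_len(n_cont), function(i)
          sample.int(nchar(sim$contaminants[fam[i]]) - wl[i] + 1L, 1L),
          integer(1))
        inserts <- c(inserts,
                     substring(sim$contaminants[fam], st, st + wl - 1L))
      }
      n_junk <- counts[n_arm + 2L]
      if (n_junk > 0)
        inserts <- c(inserts,
                     random_dna_vec(sample(20:23, n_junk, replace = TRUE)))

      rd <- substr(paste0(inserts, tail_seq), 1L, cfg$read_len)
      # substitution errors, applied eventwise (vectorized); the rare read
      # drawing several events keeps the last one
      if (cfg$error_rate > 0) {
        nerr <- rbinom(length(rd), nchar(rd), cfg$error_rate)
        ev_read <- rep.int(seq_along(rd), nerr)
        if (length(ev_read)) {
          ev_pos <- ceiling(runif(length(ev_read)) * nchar(rd)[ev_read])
          cur <- substring(rd[ev_read], ev_pos, ev_pos)
          others <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                             "A", "C", "G"), nrow = 4L, byrow = TRUE,
                           dimnames = list(DNA_BASES, NULL))
          newb <- others[cbind(match(cur, DNA_BASES),
                               sample.int(3L, length(ev_read),
                                          replace = TRUE))]
          x <- rd[ev_read]
          substring(x, ev_pos, ev_pos) <- newb
          rd[ev_read] <- x
        }
      }
      reads[[tis]] <- rd[sample.int(length(rd))]
    }
    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files <- setNames(file.path(out_dir, paste0(cfg$tissues, ".fastq")),
                        cfg$tissues)
      for (tis in cfg$tissues)
        write_fastq(reads[[tis]], files[[tis]],
                    ids = sprintf("%s_%06d", tis,
                                  seq_along(reads[[tis]])))
    }
    list(reads = reads, realized = realized, files = files)
  })
}

#' Simulate a block-structured mRNA expression matrix
#'
#' Generates `k_true` co-expression clusters, each with a distinct
#' tissue-block mean profile (high in 1-3 tissues) plus multiplicative
#' log-normal noise, and a configurable fraction of flat low-covariance
#' genes that exercise the covariance filter.
#'
#' @param n_genes total genes.
#' @param k_true number of planted clusters.
#' @param tissues tissue labels.
#' @param seed RNG seed.
#' @param flat_frac fraction of flat (unstructured) genes.
#' @param noise_sd log-scale noise standard deviation for structured genes.
#' @param base baseline expression level.
#' @param high_fold fold elevation in a cluster's home tissues.
#' @return list with `matrix` (a normalized-state [expression_matrix()])
#'   and `truth` (integer cluster labels, `NA` for flat genes).
#' @export
simulate_expression_matrix <- function(n_genes = 1200L, k_true = 12L,
                                       tissues = DEFAULT_TISSUES,
                                       seed = 1L, flat_frac = 0.25,
                                       noise_sd = 0.25, base = 50,
                                       high_fold = 8) {
  if (k_true < 1L) stop("k_true must be >= 1")
  stopifnot(n_genes >= k_true)
  with_seed(derive_seed(seed, 3L), {
    nt <- length(tissues)
    n_flat <- round(n_genes * flat_frac)
    n_struct <- n_genes - n_flat
    # distinct home-tissue subsets per cluster
    patterns <- list()
    while (length(patterns) < k_true) {
      s <- sort(sample(nt, sample(1:3, 1L)))
      key <- paste(s, collapse = ",")
      if (!key %in% names(patterns)) patterns[[key]] <- s
    }
    labels <- rep(seq_len(k_true), length.out = n_struct)
    mu <- matrix(base, n_struct, nt)
    for (g in seq_len(n_struct)) mu[g, patterns[[labels[g]]]] <-
      base * high_fold
    m_struct <- mu * exp(matrix(rnorm(n_struct * nt, 0, noise_sd),
                                n_struct, nt))
    m_flat <- base * exp(matrix(rnorm(n_flat * nt, 0, 0.05), n_flat, nt))
    m <- rbind(m_struct, m_flat)
    rownames(m) <- sprintf("gene%04d", seq_len(n_genes))
    colnames(m) <- tissues
    truth <- c(labels, rep(NA_integer_, n_flat))
    names(truth) <- rownames(m)
    ord <- sample.int(n_genes)
    list(matrix = expression_matrix(m[ord, ], state = "normalized",
                                    ledger = "simulated (block-structured)"),
         truth = truth[ord])
  })
}

#' Simulate concentrated position weight matrices
#'
#' Each column has one dominant base at frequency `dominance` with the
#' remainder spread evenly, yielding high-information motifs.
#'
#' @param n number of PWMs.
#' @param L motif length.
#' @param seed RNG seed.
#' @param dominance dominant-base frequency per column.
#' @return list of [pwm()] objects.
#' @export
simulate_pwms <- function(n = 1L, L = 10L, seed = 1L, dominance = 0.85) {
  with_seed(derive_seed(seed, 4L), {
    lapply(seq_len(n), function(i) {
      counts <- matrix(round(100 * (1 - dominance) / 3), 4L, L,
                       dimnames = list(DNA_BASES, NULL))
      dom <- sample.int(4L, L, replace = TRUE)
      counts[cbind(dom, seq_len(L))] <- round(100 * dominance)
      pwm(counts, name = sprintf("TF%02d", i))
    })
  })
}

#' Simulate promoter sets with planted PWM sites
#'
#' Foreground and background promoters are i.i.d. uniform nucleotide
#' sequences; for every PWM, consensus sites are planted at Poisson rates
#' (`planted_rate_*` sites per promoter per PWM) at uniform offsets on a
#' random strand, all recorded in the truth table.
#'
#' @param n_fg,n_bg numbers of foreground / background promoters.
#' @param pwms list of [pwm()] objects (defaults to one simulated PWM).
#' @param planted_rate_fg,planted_rate_bg expected planted sites per
#'   promoter per PWM.
#' @param promoter_len promoter length (bp).
#' @param seed RNG seed.
#' @return list with `fg`, `bg` (named character vectors), `pwms`, and
#'   `truth` (data frame set/gene/pwm/offset/strand).
#' @export
simulate_promoters_and_pwms <- function(n_fg = 51L, n_bg = 2984L,
                                        pwms = NULL,
                                        planted_rate_fg = 0.5,
                                        planted_rate_bg = 0.5,
                                        promoter_len = 2000L, seed = 1L) {
  pwms <- pwms %||% simulate_pwms(1L, 10L, seed)
  if (any(vapply(pwms, function(p) ncol(p$counts), 1L) > promoter_len))
    stop("planted site longer than promoter")
  with_seed(derive_seed(seed, 5L), {
    gen_set <- function(n, prefix, rate) {
      seqs <- setNames(random_dna(n, promoter_len),
                       sprintf("%s_%04d", prefix, seq_len(n)))
      truth <- list()
      for (p in pwms) {
        L <- ncol(p$counts)
        cons <- paste(DNA_BASES[apply(p$freq, 2L, which.max)],
                      collapse = "")
        k <- rpois(n, rate)
        total <- sum(k)
        if (total == 0L) next
        gene_i <- rep.int(seq_len(n), k)
        off <- sample.int(promoter_len - L + 1L, total, replace = TRUE)
        strand <- sample(c("+", "-"), total, replace = TRUE)
        site <- ifelse(strand == "+", cons, revcomp(cons))
        for (s in seq_len(total))
          substr(seqs[[gene_i[s]]], off[s], off[s] + L - 1L) <- site[s]
        truth[[length(truth) + 1L]] <- data.frame(
          gene = names(seqs)[gene_i], pwm = p$name, offset = off,
          strand = strand, stringsAsFactors = FALSE)
      }
      truth <- if (length(truth)) do.call(rbind, truth)
               else data.frame(gene = character(0), pwm = character(0),
                               offset = integer(0), strand = character(0))
      list(seqs = seqs, truth = truth)
    }
    fg <- gen_set(n_fg, "fg", planted_rate_fg)
    bg <- gen_set(n_bg, "bg", planted_rate_bg)
    truth <- rbind(cbind(set = rep("fg", nrow(fg$truth)), fg$truth),
                   cbind(set = rep("bg", nrow(bg$truth)), bg$truth))
    list(fg = fg$seqs, bg = bg$seqs, pwms = pwms, truth = truth)
  })
}

#' Write all simulation artifacts to disk
#'
#' Emits the genome, conserved catalog and contaminant FASTA files, truth
#' loci as GFF3, truth profiles as TSV, and per-tissue FASTQ libraries.
#'
#' @param sim a `mirna_sim`.
#' @param libs result of [simulate_small_rna_libraries()] (generated if
#'   NULL).
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, libs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  libs <- libs %||% simulate_small_rna_libraries(sim, file.path(dir, "fastq"))
  if (is.null(libs$files))
    libs$files <- simulate_small_rna_libraries(
      sim, file.path(dir, "fastq"))$files
  paths <- c(genome = file.path(dir, "genome.fa"),
             catalog = file.path(dir, "catalog.fa"),
             contaminants = file.path(dir, "contaminants.fa"),
             loci = file.path(dir, "truth_loci.gff3"),
             profiles = file.path(dir, "truth_profiles.tsv"),
             realized = file.path(dir, "truth_realized_counts.tsv"))
  write_fasta(sim$genome, paths[["genome"]])
  write_fasta(setNames(sim$catalog$sequence, sim$catalog$family),
              paths[["catalog"]])
  write_fasta(sim$contaminants, paths[["contaminants"]])
  write_loci_gff3(sim$truth$loci, paths[["loci"]])
  write_tsv(data.frame(locus_id = rownames(sim$truth$profiles),
                       sim$truth$profiles, check.names = FALSE),
            paths[["profiles"]])
  write_tsv(data.frame(arm_id = rownames(libs$realized), libs$realized,
                       check.names = FALSE), paths[["realized"]])
  invisible(c(paths, libs$files))
}
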