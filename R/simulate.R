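# Synthetic-data generator: emulates the signal and artifact structure of
# strand-specific plastid RNA-seq at pileup level — binomial C>U editing at
# site-specific efficiencies, dUTP second-strand carryover mirrored on the
# opposite strand, rRNA reverse-transcriptase misincorporation with a
# multi-type substitution spectrum, splice-junction-proximal mismatches, and
# uniform base error — across total, rRNA-depleted and poly(A) library
# strategies.

SUBSTITUTION_TYPES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                        "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

# default rRNA misincorporation spectrum: 10 active substitution types with
# C>T held at 6.25% and transitions (U>C, A>G, G>A) dominating
DEFAULT_RRNA_SPECTRUM <- c(
  "C>T" = 0.0625, "T>C" = 0.20, "A>G" = 0.20, "G>A" = 0.20,
  "T>A" = 0.10, "G>T" = 0.05, "C>A" = 0.05, "A>C" = 0.05,
  "T>G" = 0.05, "G>C" = 0.0375)

#' Simulation configuration
#'
#' Assembles and validates the parameter set for the synthetic plastome
#' generator. Defaults reflect the study conditions the pipeline is designed
#' for: three biological samples sequenced with total and rRNA-depleted
#' strand-specific libraries at ~500x coding-strand depth, 40 C>U edit sites
#' with efficiencies between 0.15 and 0.95, second-strand carryover at 1/100
#' of the edited signal, an rRNA misincorporation spectrum, junction-proximal
#' mismatch artifacts, and a uniform 1e-3 base error. The poly(A) (`mrna`)
#' strategy, when enabled, defaults to 2% of total-RNA depth.
#'
#' @param seed Integer seed; propagates to all stochastic draws.
#' @param genome_length Plastome length in bp (must fit the gene content).
#' @param n_genes Number of genes (last is an rRNA locus; one CDS gene is
#'   multi-exon). Must be >= 3.
#' @param samples Character vector of sample ids.
#' @param strategies Library strategies to simulate; subset of
#'   `c("total", "rrna_depleted", "mrna")`.
#' @param coverage Named mean coding-strand depths per strategy.
#' @param rrna_boost Named multiplicative depth factors for rRNA loci.
#' @param n_edits Number of planted edit sites.
#' @param efficiency_range Range of per-site editing efficiencies (uniform).
#' @param edit_substitution Planted substitution, `"C>T"` or `"T>C"`
#'   (transcript orientation).
#' @param carryover_rate rho: fraction of a site's edited signal mirrored on
#'   the opposite strand as the complementary substitution.
#' @param n_rrna_sites Number of rRNA modification artifact sites.
#' @param rrna_rate Per-site alt fraction at rRNA artifact sites.
#' @param rrna_spectrum Named probability vector over substitution types.
#' @param rrna_noncoding_prob Probability an rRNA artifact sits on the
#'   noncoding strand of the rRNA locus.
#' @param junction_window Exon-side window (bp) for junction artifacts.
#' @param junction_rate Mismatch fraction at junction artifact positions.
#' @param junction_per_boundary Artifact positions per exon-intron boundary.
#' @param base_error Uniform per-base sequencing error rate.
#' @param intergenic_depth Mean background depth outside genes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 24000L,
                       n_genes = 8L,
                       samples = c("s1", "s2", "s3"),
                       strategies = c("total", "rrna_depleted"),
                       coverage = c(total = 500, rrna_depleted = 500, mrna = 10),
                       rrna_boost = c(total = 50, rrna_depleted = 5, mrna = 0.2),
                       n_edits = 40L,
                       efficiency_range = c(0.15, 0.95),
                       edit_substitution = "C>T",
                       carryover_rate = 1 / 100,
                       n_rrna_sites = 12L,
                       rrna_rate = 0.3,
                       rrna_spectrum = DEFAULT_RRNA_SPECTRUM,
                       rrna_noncoding_prob = 0.9,
                       junction_window = 6L,
                       junction_rate = 0.25,
                       junction_per_boundary = 2L,
                       base_error = 1e-3,
                       intergenic_depth = 2) {
  stopifnot(n_genes >= 3L,
            all(strategies %in% c("total", "rrna_depleted", "mrna")),
            all(strategies %in% names(coverage)),
            all(strategies %in% names(rrna_boost)),
            length(efficiency_range) == 2L,
            all(efficiency_range >= 0), all(efficiency_range <= 1),
            carryover_rate >= 0, carryover_rate <= 1,
            base_error >= 0, base_error <= 1,
            edit_substitution %in% c("C>T", "T>C"))
  if (!all(names(rrna_spectrum) %in% SUBSTITUTION_TYPES)) {
    stop("rrna_spectrum names must be directed substitution types")
  }
  if (abs(sum(rrna_spectrum) - 1) > 1e-8) stop("rrna_spectrum must sum to 1")
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes), samples = samples,
              strategies = strategies, coverage = coverage,
              rrna_boost = rrna_boost, n_edits = as.integer(n_edits),
              efficiency_range = efficiency_range,
              edit_substitution = edit_substitution,
              carryover_rate = carryover_rate,
              n_rrna_sites = as.integer(n_rrna_sites), rrna_rate = rrna_rate,
              rrna_spectrum = rrna_spectrum,
              rrna_noncoding_prob = rrna_noncoding_prob,
              junction_window = as.integer(junction_window),
              junction_rate = junction_rate,
              junction_per_boundary = as.integer(junction_per_boundary),
              base_error = base_error, intergenic_depth = intergenic_depth)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("coverage", "rrna_boost", "rrna_spectrum")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(sim_config, vals)
}

NONSTOP_CODONS <- setdiff(
  as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                  c("A","C","G","T"), paste0)),
  c("TAA", "TAG", "TGA"))

random_cds <- function(n_codons) {
  paste0(c(sample(NONSTOP_CODONS, n_codons - 1L, replace = TRUE), "TAA"),
         collapse = "")
}

random_bases <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a plastome reference with gene models and a truth site set
#'
#' Generates a reproducible synthetic plastome: `n_genes - 1` protein-coding
#' genes on alternating strands (the third gene carries an intron), one rRNA
#' locus, planted edit sites at coding-strand bases matching the configured
#' substitution, rRNA modification artifact sites drawn from the configured
#' spectrum, and junction-proximal artifact positions. Edit sites are kept at
#' least 15 bp away from exon-intron boundaries so editing and junction
#' artifacts remain disjoint truth classes.
#'
#' @param config A [sim_config()].
#' @return list with `genome`, `features`, and `truth`: a data.frame with one
#'   row per planted event (`class` in edit/rrna_artifact/junction_artifact,
#'   plus `pos`, `strand`, `ref`, `alt` in transcript orientation, and `rate`
#'   = efficiency or mismatch rate). Carryover manifests per experiment and
#'   is recorded by [simulate_pileup()].
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length < 10 * config$n_genes * 300) {
    stop("genome_length must be >= ", 10 * config$n_genes * 300,
         " for ", config$n_genes, " genes")
  }
  set.seed(config$seed)
  n_cds <- config$n_genes - 1L
  specs <- list()
  for (i in seq_len(n_cds)) {
    g <- sprintf("g%02d", i)
    sp <- list(gene = g, ftype = "CDS",
               strand = if (i %% 2L == 1L) "+" else "-",
               seq = random_cds(300L))
    if (i == 3L) {  # one multi-exon gene
      sp$intron_after <- 450L
      sp$intron_seq <- random_bases(300L)
    }
    specs[[g]] <- sp
  }
  specs$rrn1 <- list(gene = "rrn1", ftype = "rRNA", strand = "+",
                     seq = random_bases(1500L))
  built <- assemble_genome(specs, genome_id = "plastome_sim", spacer = 200L,
                           genome_length = config$genome_length)
  genome <- built$genome
  features <- built$features

  truth <- list()
  # --- planted edits: coding-strand positions whose base matches ref ------
  ref_base <- substring(config$edit_substitution, 1L, 1L)
  alt_base <- substring(config$edit_substitution, 3L, 3L)
  cds <- features[features$ftype == "CDS", , drop = FALSE]
  introns <- features[features$ftype == "intron", , drop = FALSE]
  boundary_pts <- c(introns$start, introns$end,
                    introns$start - 1L, introns$end + 1L)
  cand_pos <- integer(0); cand_strand <- character(0)
  for (i in seq_len(nrow(cds))) {
    p <- seq.int(cds$start[i], cds$end[i])
    cand_pos <- c(cand_pos, p)
    cand_strand <- c(cand_strand, rep(cds$strand[i], length(p)))
  }
  ok <- strand_base(genome, cand_pos, cand_strand) == ref_base
  if (length(boundary_pts)) {
    near <- vapply(cand_pos, function(p) min(abs(p - boundary_pts)) <= 15L,
                   logical(1))
    ok <- ok & !near
  }
  cand_pos <- cand_pos[ok]; cand_strand <- cand_strand[ok]
  if (length(cand_pos) < config$n_edits) {
    stop("not enough eligible ", ref_base, " positions to place ",
         config$n_edits, " edits")
  }
  if (config$n_edits > 0L) {
    pick <- sample.int(length(cand_pos), config$n_edits)
    eff <- stats::runif(config$n_edits, config$efficiency_range[1L],
                        config$efficiency_range[2L])
    truth$edit <- data.frame(
      class = "edit", pos = cand_pos[pick], strand = cand_strand[pick],
      ref = ref_base, alt = alt_base, rate = eff)
  }

  # --- rRNA modification artifact sites -----------------------------------
  if (config$n_rrna_sites > 0L) {
    rr <- features[features$ftype == "rRNA", , drop = FALSE][1L, ]
    rpos <- seq.int(rr$start, rr$end)
    used <- integer(0)
    rows <- vector("list", config$n_rrna_sites)
    for (k in seq_len(config$n_rrna_sites)) {
      ty <- sample(names(config$rrna_spectrum), 1L,
                   prob = config$rrna_spectrum)
      st <- if (stats::runif(1) < config$rrna_noncoding_prob)
        setdiff(c("+", "-"), rr$strand) else rr$strand
      rref <- substring(ty, 1L, 1L)
      avail <- rpos[!(rpos %in% used) &
                    strand_base(genome, rpos, st) == rref]
      if (!length(avail)) stop("cannot place rRNA artifact of type ", ty)
      p <- if (length(avail) == 1L) avail else sample(avail, 1L)
      used <- c(used, p)
      rows[[k]] <- data.frame(class = "rrna_artifact", pos = p, strand = st,
                              ref = rref, alt = substring(ty, 3L, 3L),
                              rate = config$rrna_rate)
    }
    truth$rrna <- do.call(rbind, rows)
  }

  # --- junction-proximal artifacts ----------------------------------------
  if (nrow(introns) && config$junction_per_boundary > 0L &&
      config$junction_rate > 0) {
    rows <- list()
    for (i in seq_len(nrow(introns))) {
      st <- introns$strand[i]
      for (side in c("left", "right")) {
        exon_edge <- if (side == "left") introns$start[i] - 1L
                     else introns$end[i] + 1L
        dirn <- if (side == "left") -1L else 1L
        offs <- sample.int(config$junction_window,
                           config$junction_per_boundary)
        for (o in offs) {
          p <- exon_edge + dirn * (o - 1L)
          rb <- strand_base(genome, p, st)
          ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            class = "junction_artifact", pos = p, strand = st,
            ref = rb, alt = ab, rate = config$junction_rate)
        }
      }
    }
    jn <- do.call(rbind, rows)
    jn <- jn[!duplicated(jn$pos), , drop = FALSE]
    jn <- jn[!(jn$pos %in% truth$edit$pos), , drop = FALSE]
    truth$junction <- jn
  }

  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(class = character(0), pos = integer(0),
                        strand = character(0), ref = character(0),
                        alt = character(0), rate = numeric(0))
  }
  rownames(truth) <- NULL
  list(genome = genome, features = features, truth = truth)
}

# forward-orientation base of a transcript-orientation base on a strand
forward_base <- function(base, strand) {
  out <- base
  minus <- strand == "-"
  out[minus] <- complement_base(base[minus])
  out
}

#' Simulate strand-specific pileups for all samples and libraries
#'
#' Per experiment (sample x strategy), per-strand depth is drawn as
#' Poisson(strategy mean) across transcribed loci (rRNA loci are scaled by
#' the strategy's rRNA boost; intergenic background uses
#' `intergenic_depth`). At edit sites the coding-strand edited count is
#' Binomial(depth, e); the opposite strand receives the complementary
#' substitution at Binomial(depth, rho * e) (dUTP second-strand carryover).
#' rRNA artifact sites and junction windows emit alt reads at their
#' configured rates, and uniform base error is applied everywhere.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return list with `pileups` (data.frame: sample, library, pos, strand,
#'   nA, nC, nG, nT; forward-orientation counts, zero-depth rows dropped)
#'   and `events`: per-experiment realized truth events (class, sample,
#'   library, pos, strand, ref, alt, var_reads, depth), including
#'   `carryover` rows wherever carryover manifested with >= 1 read.
#' @export
simulate_pileup <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genome <- reference$genome
  features <- reference$features
  truth <- reference$truth
  glen <- genome$length

  # mean-depth template per strategy: depth profile over all positions
  rr <- features[features$ftype == "rRNA", , drop = FALSE]
  in_rrna <- rep(FALSE, glen)
  for (i in seq_len(nrow(rr))) in_rrna[rr$start[i]:rr$end[i]] <- TRUE
  in_gene <- rep(FALSE, glen)  # whole transcribed units, introns included
  for (i in seq_len(nrow(features))) {
    in_gene[features$start[i]:features$end[i]] <- TRUE
  }

  fwd <- strsplit(genome$bases, "")[[1L]]
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)

  pile <- list(); events <- list()
  for (smp in config$samples) {
    for (lib in config$strategies) {
      mu <- rep(config$intergenic_depth, glen)
      mu[in_gene] <- config$coverage[[lib]]
      mu[in_rrna] <- config$coverage[[lib]] * config$rrna_boost[[lib]]
      # per-strand Poisson depth over both strands
      dep <- list("+" = stats::rpois(glen, mu), "-" = stats::rpois(glen, mu))
      cnt <- list("+" = matrix(0L, glen, 4L), "-" = matrix(0L, glen, 4L))
      for (st in c("+", "-")) {
        cnt[[st]][cbind(seq_len(glen), base_idx[fwd])] <- dep[[st]]
      }
      move <- function(st, pos, from_fwd, to_fwd, k) {
        i <- base_idx[from_fwd]; j <- base_idx[to_fwd]
        k <- pmin(k, cnt[[st]][cbind(pos, i)])
        cnt[[st]][cbind(pos, i)] <<- cnt[[st]][cbind(pos, i)] - k
        cnt[[st]][cbind(pos, j)] <<- cnt[[st]][cbind(pos, j)] + k
        k
      }
      # planted events
      for (cl in unique(truth$class)) {
        tr <- truth[truth$class == cl, , drop = FALSE]
        d <- mapply(function(p, s) dep[[s]][p], tr$pos, tr$strand)
        k <- stats::rbinom(nrow(tr), d, tr$rate)
        ffrom <- forward_base(tr$ref, tr$strand)
        fto <- forward_base(tr$alt, tr$strand)
        for (i in seq_len(nrow(tr))) {
          k[i] <- move(tr$strand[i], tr$pos[i], ffrom[i], fto[i], k[i])
        }
        events[[length(events) + 1L]] <- data.frame(
          class = cl, sample = smp, library = lib, pos = tr$pos,
          strand = tr$strand, ref = tr$ref, alt = tr$alt,
          var_reads = k, depth = d)
      }
      # dUTP second-strand carryover: complementary signal opposite edits
      if (config$carryover_rate > 0) {
        ed <- truth[truth$class == "edit", , drop = FALSE]
        opp <- ifelse(ed$strand == "+", "-", "+")
        d2 <- mapply(function(p, s) dep[[s]][p], ed$pos, opp)
        k2 <- stats::rbinom(nrow(ed), d2, config$carryover_rate * ed$rate)
        # same forward alt base as the source edit, deposited opposite
        ffrom <- forward_base(ed$ref, ed$strand)
        fto <- forward_base(ed$alt, ed$strand)
        for (i in seq_len(nrow(ed))) {
          if (k2[i] > 0L) k2[i] <- move(opp[i], ed$pos[i], ffrom[i], fto[i], k2[i])
        }
        keep <- k2 > 0L
        if (any(keep)) {
          events[[length(events) + 1L]] <- data.frame(
            class = "carryover", sample = smp, library = lib,
            pos = ed$pos[keep], strand = opp[keep],
            ref = complement_base(ed$ref[keep]),
            alt = complement_base(ed$alt[keep]),
            var_reads = k2[keep], depth = d2[keep])
        }
      }
      # uniform base error
      if (config$base_error > 0) {
        for (st in c("+", "-")) {
          ne <- stats::rbinom(glen, dep[[st]], config$base_error)
          hit <- which(ne > 0L)
          for (p in hit) {
            others <- setdiff(c("A", "C", "G", "T"), fwd[p])
            split <- stats::rmultinom(1L, ne[p], rep(1 / 3, 3))[, 1L]
            for (b in 1:3) {
              if (split[b] > 0L) move(st, p, fwd[p], others[b], split[b])
            }
          }
        }
      }
      for (st in c("+", "-")) {
        keep <- dep[[st]] > 0L
        pile[[length(pile) + 1L]] <- data.frame(
          sample = smp, library = lib, pos = which(keep), strand = st,
          nA = cnt[[st]][keep, 1L], nC = cnt[[st]][keep, 2L],
          nG = cnt[[st]][keep, 3L], nT = cnt[[st]][keep, 4L])
      }
    }
  }
  pileups <- do.call(rbind, pile)
  rownames(pileups) <- NULL
  events <- do.call(rbind, events)
  rownames(events) <- NULL
  list(pileups = pileups, events = events)
}

#' One-call synthetic dataset
#'
#' Runs [simulate_reference()] and [simulate_pileup()] under one config.
#'
#' @param config A [sim_config()].
#' @return list with `genome`, `features`, `truth`, `pileups`, `events`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  sim <- simulate_pileup(config, ref)
  c(ref, sim)
}

#' Write a truth table as TSV
#' @param truth Truth data.frame from [simulate_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
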