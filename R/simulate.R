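#' Sample a toy ensemble of secondary-structure pairing states
#'
#' Generates unique per-nucleotide pairing-state vectors by placing random
#' hairpin helices (stem length 3-7 nt, loop 3-8 nt) in unoccupied
#' intervals, which guarantees valid non-crossing (nested or disjoint)
#' base pairs without requiring a sequence or a thermodynamic model. The
#' first structure is designated the MFE-like reference. Externally
#' sampled structures can be supplied instead as dot-bracket strings via
#' [ensembleFromDotBracket()].
#'
#' @param length region length in nucleotides (the usual search range for
#'   structured regions is 50-75 nt, but any length >= 15 is accepted).
#' @param nStructures number of unique structures (>= 6: at least 5
#'   dominant plus infrequent ones are needed downstream).
#' @param seed optional integer seed.
#' @param maxHelices maximum helices per structure (default: enough to
#'   reach typical pairing density at the given length).
#' @return a \linkS4class{StructureEnsemble}.
#' @export
sampleEnsemble <- function(length, nStructures, seed = NULL,
                           maxHelices = max(4L, length %/% 15L)) {
  if (!is.null(seed))
    set.seed(seed)
  if (nStructures < 6L)
    stop("need at least 6 structures (>= 5 dominant plus infrequent)")
  if (length < 15L)
    stop("region too short to place a helix ensemble")
  seen <- character()
  pairing <- matrix(FALSE, nrow = 0L, ncol = length)
  tries <- 0L
  while (nrow(pairing) < nStructures) {
    tries <- tries + 1L
    if (tries > 50L * nStructures)
      stop("could not sample ", nStructures, " unique structures")
    v <- randomPairingVector(length, maxHelices)
    key <- paste(as.integer(v), collapse = "")
    if (key %in% seen)
      next
    seen <- c(seen, key)
    pairing <- rbind(pairing, v)
  }
  rownames(pairing) <- NULL
  methods::new("StructureEnsemble", pairing = pairing, mfeIndex = 1L)
}

# One pairing-state vector: hairpins dropped into fully unpaired intervals
# (nested-or-disjoint placement keeps pairs non-crossing) until a target
# pairing density typical of folded RNA (40-65% paired) is reached.
randomPairingVector <- function(len, maxHelices) {
  v <- rep(FALSE, len)
  target <- runif(1L, 0.4, 0.65)
  for (h in seq_len(maxHelices)) {
    if (mean(v) >= target)
      break
    stem <- sample(3:7, 1L)
    loop <- sample(3:8, 1L)
    span <- 2L * stem + loop
    if (span > len)
      next
    for (attempt in 1:20) {
      i <- sample.int(len - span + 1L, 1L)
      window <- i:(i + span - 1L)
      if (!any(v[window])) {
        v[c(i:(i + stem - 1L), (i + span - stem):(i + span - 1L))] <- TRUE
        break
      }
    }
  }
  v
}

#' Build a StructureEnsemble from dot-bracket strings
#'
#' Hook for externally sampled structures: a plain-text vector (or file,
#' one structure per line) of dot-bracket strings; brackets are paired,
#' dots unpaired. The first structure is taken as the MFE-like reference.
#'
#' @param structures character vector of dot-bracket strings, or a path to
#'   a text file with one structure per line.
#' @return a \linkS4class{StructureEnsemble}.
#' @export
ensembleFromDotBracket <- function(structures) {
  if (length(structures) == 1L && file.exists(structures))
    structures <- readLines(structures)
  structures <- structures[nzchar(structures)]
  if (length(unique(nchar(structures))) != 1L)
    stop("all structures must have the same length")
  pairing <- t(vapply(strsplit(structures, ""),
                      function(ch) ch != ".", logical(nchar(structures[1L]))))
  pairing <- unique(pairing)
  methods::new("StructureEnsemble", pairing = pairing, mfeIndex = 1L)
}

#' Assign ensemble weights to the structures of two groups
#'
#' Each group receives up to \code{nDominant} dominant structures whose
#' total ensemble weight is drawn uniformly from
#' \code{dominantMassRange}; the dominant sets of the two groups are
#' disjoint (and exclude the MFE-like reference), which is what makes the
#' groups' reactivity profiles differ. The remaining mass is randomly
#' distributed among the infrequent structures, and the shared MFE-like
#' structure receives \code{mfeWeight} in both groups - raising it towards
#' 1 in both groups makes the two ensembles (and hence the group profiles)
#' converge, increasing between-group correlation.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param dominantMassRange total dominant weight range (default
#'   c(0.33, 0.66); scaled by the mass left after \code{mfeWeight}).
#' @param mfeWeight weight of the MFE-like structure in both groups
#'   (default 0).
#' @param nDominant maximum dominant structures per group (default 5; the
#'   actual count is drawn uniformly from 1..nDominant, "up to"
#'   \code{nDominant} dominant structures, and reduced when the ensemble
#'   is small).
#' @param seed optional integer seed.
#' @return list with numeric weight vectors \code{A} and \code{B} (each
#'   summing to 1) and the dominant index sets \code{dominantA},
#'   \code{dominantB}.
#' @export
assignWeights <- function(ensemble, dominantMassRange = c(0.33, 0.66),
                          mfeWeight = 0, nDominant = 5L, seed = NULL) {
  if (!is.null(seed))
    set.seed(seed)
  n <- nrow(ensemble@pairing)
  avail <- setdiff(seq_len(n), ensemble@mfeIndex)
  k <- min(sample.int(nDominant, 1L), floor(length(avail) / 2))
  if (k < 1L)
    stop("dominant sets for the two groups cannot be disjoint")
  dominantA <- sample(avail, k)
  dominantB <- sample(setdiff(avail, dominantA), k)
  list(A = weightVector(n, dominantA, ensemble@mfeIndex, mfeWeight,
                        dominantMassRange),
       B = weightVector(n, dominantB, ensemble@mfeIndex, mfeWeight,
                        dominantMassRange),
       dominantA = dominantA, dominantB = dominantB)
}

# Single weight vector: mfeWeight on the reference, a dominant mass drawn
# from `massRange` (of the non-MFE budget) split randomly over `dominant`,
# the rest split randomly over the remaining structures.
weightVector <- function(n, dominant, mfeIndex, mfeWeight, massRange) {
  if (mfeWeight < 0 || mfeWeight > 1)
    stop("mfeWeight must lie in [0, 1]")
  w <- numeric(n)
  w[mfeIndex] <- mfeWeight
  budget <- 1 - mfeWeight
  dm <- runif(1L, massRange[1L], massRange[2L]) * budget
  splitD <- stats::rexp(length(dominant))
  w[dominant] <- dm * splitD / sum(splitD)
  infrequent <- setdiff(seq_len(n), c(dominant, mfeIndex))
  if (length(infrequent)) {
    splitI <- stats::rexp(length(infrequent))
    w[infrequent] <- (budget - dm) * splitI / sum(splitI)
  } else {
    w[dominant] <- w[dominant] * budget / dm
  }
  w
}

#' Perturb ensemble weights to create a replicate
#'
#' Symmetric multiplicative lognormal noise followed by renormalization:
#' \code{w * exp(noiseScale * z)}, z standard normal, rescaled to sum 1.
#' The result is non-negative and reduces to the input when
#' \code{noiseScale = 0}. Larger scales lower the expected within-group
#' correlation of the emitted replicate profiles.
#'
#' @param weights non-negative weight vector summing to 1.
#' @param noiseScale noise scale >= 0 (log-sd of the multiplicative
#'   factor).
#' @param seed optional integer seed.
#' @return perturbed weight vector summing to 1.
#' @export
perturbWeights <- function(weights, noiseScale, seed = NULL) {
  if (!is.null(seed))
    set.seed(seed)
  if (noiseScale < 0)
    stop("noiseScale must be >= 0")
  if (noiseScale == 0)
    return(weights)
  w <- weights * exp(noiseScale * rnorm(length(weights)))
  w / sum(w)
}

#' Parameterized paired/unpaired emission model
#'
#' Lognormal reactivity-emission distributions for paired and unpaired
#' nucleotides. The defaults put the unpaired median an order of magnitude
#' above the paired median, the qualitative shape of DMS/SHAPE reactivity
#' mixtures.
#'
#' @param pairedMeanlog,pairedSdlog lognormal parameters for paired
#'   nucleotides (default meanlog log(0.1), sdlog 0.8).
#' @param unpairedMeanlog,unpairedSdlog parameters for unpaired
#'   nucleotides (default meanlog 0, sdlog 0.8).
#' @return an \linkS4class{EmissionModel}.
#' @export
emissionModel <- function(pairedMeanlog = log(0.1), pairedSdlog = 0.8,
                          unpairedMeanlog = 0, unpairedSdlog = 0.8) {
  methods::new("EmissionModel", pairedMeanlog = pairedMeanlog,
               pairedSdlog = pairedSdlog, unpairedMeanlog = unpairedMeanlog,
               unpairedSdlog = unpairedSdlog)
}

#' Sample per-structure reactivity profiles
#'
#' One reactivity profile per structure in the ensemble, drawn from the
#' emission model according to each nucleotide's pairing state. Replicate
#' samples that share these per-structure profiles and differ only in
#' their ensemble weights are correlated, as replicates of real
#' structure-probing experiments are.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param model an \linkS4class{EmissionModel}.
#' @param seed optional integer seed.
#' @return numeric matrix, nucleotides x structures.
#' @export
structureReactivities <- function(ensemble, model = emissionModel(),
                                  seed = NULL) {
  if (!is.null(seed))
    set.seed(seed)
  pairing <- t(ensemble@pairing)       # nucleotides x structures
  n <- length(pairing)
  vals <- ifelse(pairing,
                 rlnorm(n, model@pairedMeanlog, model@pairedSdlog),
                 rlnorm(n, model@unpairedMeanlog, model@unpairedSdlog))
  matrix(vals, nrow = nrow(pairing))
}

#' Emit one ensemble-averaged reactivity profile
#'
#' Per-structure profiles are sampled from the emission model and combined
#' as the ensemble-weighted average \eqn{r_k = \sum_j w_j r_{kj}}.
#' Optionally, bases not probed by the reagent are masked (DMS mode) and
#' the profile is 2-8\% normalized.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param weights ensemble weight vector summing to 1.
#' @param model an \linkS4class{EmissionModel}.
#' @param seed optional integer seed.
#' @param sequence optional nucleotide string for base-selective masking.
#' @param probedBases probed bases when \code{sequence} is given.
#' @param normalize apply 2-8\% normalization (default FALSE).
#' @param structureProfiles optional pre-sampled per-structure profile
#'   matrix from [structureReactivities()] (shared across replicates to
#'   induce correlation).
#' @return numeric reactivity profile.
#' @export
emitProfile <- function(ensemble, weights, model = emissionModel(),
                        seed = NULL, sequence = NULL,
                        probedBases = c("A", "C"), normalize = FALSE,
                        structureProfiles = NULL) {
  if (!is.null(seed))
    set.seed(seed)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1")
  if (is.null(structureProfiles))
    structureProfiles <- structureReactivities(ensemble, model)
  profile <- as.numeric(structureProfiles %*% weights)
  if (!is.null(sequence))
    profile <- maskBaseSelective(profile, sequence, probedBases)
  if (normalize)
    profile <- normalize28(profile)$values
  profile
}

#' Back-calculate treated counts from a reactivity profile
#'
#' Inverts the reactivity calculation so simulated profiles can be
#' expressed as count data: raw reactivities are recovered by scaling the
#' profile to the transcript's hit rate \eqn{h_t} (the total modification
#' rate, \eqn{r_k h_t / \sum_k r_k}), the untreated detection rates are
#' added to give treated detection rates, and multiplying by the treated
#' local coverages and rounding yields integer treated counts. Untreated
#' counts and all coverages are preserved unchanged. Profile positions
#' that are missing contribute no modification signal (background only).
#'
#' @param values normalized reactivity profile.
#' @param hitRate transcript-level total modification rate \eqn{h_t > 0}.
#' @param treatedCoverage integer treated local coverages.
#' @param untreatedCount,untreatedCoverage untreated sample data,
#'   preserved in the output.
#' @return a [countProfile()].
#' @export
backCalculateCounts <- function(values, hitRate, treatedCoverage,
                                untreatedCount, untreatedCoverage) {
  if (hitRate <= 0)
    stop("hit rate must be positive")
  tot <- sum(values, na.rm = TRUE)
  if (!is.finite(tot) || tot == 0)
    stop("profile sums to zero; cannot distribute the hit rate")
  raw <- values * hitRate / tot
  raw[is.na(raw)] <- 0
  untreatedRate <- ifelse(untreatedCoverage > 0,
                          untreatedCount / untreatedCoverage, 0)
  treatedRate <- pmin(raw + untreatedRate, 1)
  countProfile("back-calculated",
               treated_count = as.integer(round(treatedRate *
                                                  treatedCoverage)),
               treated_coverage = treatedCoverage,
               untreated_count = untreatedCount,
               untreated_coverage = untreatedCoverage)
}

#' Generate a correlated-replicate reactivity dataset with planted DRRs
#'
#' Emulates a transcriptome-wide two-group probing experiment. Each
#' transcript is tiled with independent folding domains whose lengths
#' fall in the usual search range for structured regions
#' (\code{drrLengthRange}); every domain gets its own structure ensemble
#' and ensemble weights, shared by both groups (identical generative
#' process - the null situation), and each replicate receives its own
#' weight perturbation, which creates correlated within-group variation
#' that is local rather than transcript-wide. A planted DRR is a domain
#' whose dominant-structure sets are disjoint between the groups, so the
#' groups differ there in a way that reflects a changed structure
#' ensemble rather than independent noise.
#' In DMS mode, G/U positions of the random sequences are masked, and each
#' sample is 2-8\% normalized across all its transcripts pooled.
#'
#' Replicates differ through two noise sources. Ensemble-weight
#' perturbation (\code{noiseScale}) represents biological variation in the
#' structure ensemble and acts coherently across a folding domain.
#' Measurement noise is generated at the count level: each replicate's
#' true ensemble profile is converted to treated detection rates (scaled
#' to the transcript hit rate, plus the untreated background rate),
#' treated and untreated counts are drawn binomially at finite local
#' coverage, and reactivities are recomputed through the standard
#' pipeline (detection rates, background subtraction, 2-8\%
#' normalization). This reproduces the characteristic features of real
#' data - zeros, discreteness, noise that scales with coverage - and is
#' independent between nucleotides and replicates, which keeps the null
#' \eqn{\Delta d} profile essentially uncorrelated along a transcript.
#'
#' @param nTranscripts number of transcripts (default 300).
#' @param transcriptLength transcript length in nt (default 150).
#' @param nDRR number of planted DRRs (default 100); regions are placed
#'   without overlap, at most \code{floor(transcriptLength /
#'   (max(drrLengthRange) + 1))} per transcript.
#' @param drrLengthRange DRR length range in nt (default c(50, 75)).
#' @param mA,mB replicate counts for groups A and B (default 1 and 2).
#' @param nStructures ensemble size per region (default 30).
#' @param noiseScale replicate weight-noise scale (default 0.35).
#' @param meanCoverage median local coverage per transcript (default
#'   700). Transcript averages vary lognormally around it with sd
#'   \code{coverageSpread}; transcripts carrying a planted DRR are drawn
#'   from the top 20\% of that distribution, since regions are planted
#'   only into well-covered transcripts.
#' @param coverageSpread lognormal sd of transcript-level coverage
#'   (default 1, a wide expression/coverage distribution as in
#'   transcriptome-wide libraries).
#' @param positionSpread lognormal sd of local coverage around the
#'   transcript average (default 1, the strong position-to-position
#'   coverage heterogeneity seen in real libraries).
#' @param hitRate mean treated modification rate per probed nucleotide
#'   (default 0.03, a typical DMS hit-rate level).
#' @param untreatedRate mean untreated (background) detection rate
#'   (default 0.0025; position-specific rates vary around it).
#' @param mfeWeightRange range of the shared MFE-like structure weight,
#'   drawn per region (default c(0, 0.3)); higher values raise
#'   between-group correlation.
#' @param protocol \code{"dms"} (G/U masked) or \code{"shape"} (all
#'   bases).
#' @param model an \linkS4class{EmissionModel}.
#' @param seed master integer seed; per-transcript substreams are derived
#'   from it deterministically.
#' @return list with \code{reactivity} (a \linkS4class{ReactivitySet}),
#'   \code{truth} (data.frame transcript_id, start, end, altered_start,
#'   altered_end), \code{sequences} (named character vector) and
#'   \code{counts} (per sample, per transcript [countProfile()] objects).
#' @export
generateDataset <- function(nTranscripts = 300L, transcriptLength = 150L,
                            nDRR = 100L, drrLengthRange = c(50L, 75L),
                            mA = 1L, mB = 2L, nStructures = 30L,
                            noiseScale = 0.35, meanCoverage = 700,
                            coverageSpread = 1, positionSpread = 1,
                            hitRate = 0.03, untreatedRate = 0.0025,
                            mfeWeightRange = c(0, 0.3),
                            protocol = c("dms", "shape"),
                            model = emissionModel(), seed = 1L) {
  protocol <- match.arg(protocol)
  if (max(drrLengthRange) > transcriptLength)
    stop("DRR length exceeds the transcript length: infeasible packing")
  set.seed(seed)
  txSeeds <- sample.int(.Machine$integer.max - 1L, nTranscripts)
  perTx <- max(1L, transcriptLength %/% (max(drrLengthRange) + 1L))
  if (nDRR > nTranscripts * perTx)
    stop("cannot place ", nDRR, " non-overlapping DRRs: infeasible packing")
  drrTx <- sort(sample(rep(seq_len(nTranscripts), perTx), nDRR))
  samples <- c(paste0("A", seq_len(mA)), paste0("B", seq_len(mB)))
  groups <- rep(c("A", "B"), c(mA, mB))

  profiles <- vector("list", nTranscripts)
  sequences <- character(nTranscripts)
  counts <- setNames(lapply(samples, function(s)
    setNames(vector("list", nTranscripts),
             paste0("tx", seq_len(nTranscripts)))), samples)
  truth <- list()
  for (t in seq_len(nTranscripts)) {
    set.seed(txSeeds[t])
    sequences[t] <- paste(sample(c("A", "C", "G", "U"), transcriptLength,
                                 replace = TRUE), collapse = "")
    domains <- tileDomains(transcriptLength, drrLengthRange)
    nHere <- sum(drrTx == t)
    eligible <- which(domains$len >= drrLengthRange[1L] &
                        domains$len <= drrLengthRange[2L])
    if (nHere > length(eligible))
      stop("cannot place ", nHere, " DRRs in one transcript: ",
           "infeasible packing")
    drrDomains <- if (nHere == 0L) integer(0) else
      if (length(eligible) == 1L) eligible else sample(eligible, nHere)

    m <- matrix(NA_real_, transcriptLength, length(samples),
                dimnames = list(NULL, samples))
    for (d in seq_len(nrow(domains))) {
      len <- domains$len[d]
      idx <- seq.int(domains$start[d], domains$end[d])
      ens <- sampleEnsemble(len, nStructures)
      P <- structureReactivities(ens, model)
      mfe <- runif(1L, mfeWeightRange[1L], mfeWeightRange[2L])
      if (d %in% drrDomains) {
        w <- assignWeights(ens, mfeWeight = mfe)
        baseA <- w$A
        baseB <- w$B
        topA <- ens@pairing[w$dominantA[which.max(w$A[w$dominantA])], ]
        topB <- ens@pairing[w$dominantB[which.max(w$B[w$dominantB])], ]
        altered <- which(topA != topB)
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = paste0("tx", t), start = domains$start[d],
          end = domains$end[d],
          altered_start = domains$start[d] + min(altered) - 1L,
          altered_end = domains$start[d] + max(altered) - 1L)
      } else {
        avail <- setdiff(seq_len(nStructures), ens@mfeIndex)
        base <- weightVector(nStructures,
                             dominant = sample(avail,
                                               min(sample.int(5L, 1L),
                                                   length(avail))),
                             mfeIndex = ens@mfeIndex, mfeWeight = mfe,
                             massRange = c(0.33, 0.66))
        baseA <- baseB <- base
      }
      # weight noise represents replicate-to-replicate ensemble shifts in
      # the simulated regions; outside them replicates share one ensemble
      # and differ only through counting noise, whose independence across
      # nucleotides matches the uncorrelated null delta-d of real data
      drr <- d %in% drrDomains
      for (s in seq_along(samples)) {
        base <- if (groups[s] == "A") baseA else baseB
        w <- if (drr) perturbWeights(base, noiseScale) else base
        m[idx, s] <- P %*% w
      }
    }
    # count-level measurement: true profiles -> detection rates ->
    # binomial counts at finite coverage -> recomputed reactivities;
    # DRR-carrying transcripts are drawn from the top 20% of the
    # transcript-coverage distribution, as planted regions are required
    # to be well covered
    covTx <- if (nHere > 0L)
    stats::qlnorm(runif(1L, 0.8, 1), log(meanCoverage), coverageSpread)
    else rlnorm(1L, log(meanCoverage), coverageSpread)
    hTx <- hitRate * rlnorm(1L, 0, 0.3)
    uRates <- pmin(0.5, untreatedRate *
                     rlnorm(transcriptLength, 0, 0.7))
    for (s in seq_along(samples)) {
      tCov <- pmax(1, round(covTx * rlnorm(transcriptLength, 0,
                                           positionSpread)))
      uCov <- pmax(1, round(covTx * rlnorm(transcriptLength, 0,
                                           positionSpread)))
      trueRaw <- hTx * m[, s] / mean(m[, s])
      tRate <- pmin(trueRaw + uRates, 0.9)
      tCount <- stats::rbinom(transcriptLength, tCov, tRate)
      uCount <- stats::rbinom(transcriptLength, uCov, uRates)
      counts[[s]][[t]] <- countProfile(paste0("tx", t), tCount, tCov,
                                       uCount, uCov)
      m[, s] <- rawReactivity(tCount / tCov,
                              pmin(uCount / uCov, 0.99))
    }
    if (protocol == "dms")
      m <- apply(m, 2L, maskBaseSelective, sequence = sequences[t])
    profiles[[t]] <- m
  }
  names(profiles) <- paste0("tx", seq_len(nTranscripts))
  names(sequences) <- names(profiles)

  # per-sample 2-8% normalization pooled across all transcripts
  for (s in seq_along(samples)) {
    pooled <- unlist(lapply(profiles, function(p) p[, s]))
    f <- normalize28(pooled)$f
    for (t in seq_along(profiles))
      profiles[[t]][, s] <- profiles[[t]][, s] / f
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), altered_start = integer(),
               altered_end = integer())
  list(reactivity = ReactivitySet(profiles, groups = groups),
       truth = truth, sequences = sequences, counts = counts)
}

# Tile a transcript with folding domains of lengths in `lengthRange`;
# a short remainder is folded into the final domain.
tileDomains <- function(n, lengthRange) {
  starts <- integer(0)
  lens <- integer(0)
  pos <- 1L
  while (n - pos + 1L >= lengthRange[1L]) {
    left <- n - pos + 1L
    choices <- seq.int(lengthRange[1L], min(lengthRange[2L], left))
    # prefer lengths whose remainder is empty or fits another domain, so
    # short remainders do not inflate the final domain past the range
    clean <- choices[left - choices == 0L |
                       left - choices >= lengthRange[1L]]
    if (length(clean))
      choices <- clean
    len <- if (length(choices) == 1L) choices else sample(choices, 1L)
    starts <- c(starts, pos)
    lens <- c(lens, len)
    pos <- pos + len
  }
  rest <- n - pos + 1L
  if (rest > 0L) {
    if (length(lens)) {
      lens[length(lens)] <- lens[length(lens)] + rest
    } else {
      starts <- 1L
      lens <- n
    }
  }
  data.frame(start = starts, len = lens, end = starts + lens - 1L)
}
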