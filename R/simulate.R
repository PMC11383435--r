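## Synthetic-data generators. These emulate the three data modalities of a
## knockout-depletion study: (i) single-cell time-lapse lineages in which a
## conserved protein pool is diluted by growth until a threshold arrest,
## (ii) transposon-library (TFNseq) relative-abundance time courses under the
## three growth classes, (iii) RNA-seq counts consistent with specified
## message numbers. All randomness flows from one seed per call; draws are
## consumed in a fixed, documented order (per cell in creation order; per
## gene in row order; per fraction in time order), so seeded runs are
## bit-reproducible.

#' Simulate a knockout-depletion single-cell lineage
#'
#' Cells grow exponentially in area at a per-cell rate, divide at a fixed
#' doubling area with an (optionally asymmetric) daughter split, and carry a
#' conserved protein pool: no synthesis after the knockout at t = 0, protein
#' partitioned in proportion to daughter area at division. A cell's growth
#' rate drops to \code{arrestRate} from the first sample at which its
#' protein concentration has been diluted to the functional threshold
#' \code{C0 / oTrue}. With zero noise the whole lineage therefore arrests
#' when the total progeny area reaches \code{oTrue} times the progenitor
#' area, i.e. at \code{T = log(oTrue) / k0}.
#'
#' @param k0 wild-type areal growth rate (1/h).
#' @param oTrue true overabundance (>= 1, or \code{Inf} for a never-arresting
#'   control lineage).
#' @param C0 initial protein concentration (a.u. per um^2).
#' @param doublingArea area at which a cell divides (um^2).
#' @param initialArea progenitor area at t = 0 (default half the doubling
#'   area).
#' @param nProgenitors number of independent progenitor cells.
#' @param dt sampling interval (h).
#' @param tMax simulated duration (h).
#' @param growthNoiseCV coefficient of variation of per-cell growth rate
#'   (gamma-distributed with mean \code{k0}; 0 = deterministic).
#' @param divisionAsymmetryCV CV of the daughter area fraction about 0.5
#'   (symmetric beta; 0 = equal split).
#' @param arrestRate growth rate after arrest (1/h, default 0).
#' @param hillExponent steepness of the arrest transition. \code{Inf}
#'   (default) gives the step landscape observed in knockout-depletion
#'   imaging; a finite exponent h replaces the step by the Hill factor
#'   C^h / (C^h + C_A^h) for robustness checks.
#' @param synthesisRate protein synthesis per unit area per hour (default 0,
#'   the knockout premise; positive values are a negative control that
#'   violates the dilution model).
#' @param seed integer random seed.
#' @return a \linkS4class{LineageTree}; \code{metadata()} carries the
#'   arguments plus per-cell arrest bookkeeping.
#' @examples
#' tr <- simulateLineage(k0 = log(2), oTrue = 4, dt = 0.1, tMax = 3)
#' tr
#' @export
simulateLineage <- function(k0 = log(2), oTrue = 10, C0 = 1,
                            doublingArea = 2, initialArea = doublingArea / 2,
                            nProgenitors = 1L, dt = 0.1, tMax = 10,
                            growthNoiseCV = 0, divisionAsymmetryCV = 0,
                            arrestRate = 0, hillExponent = Inf,
                            synthesisRate = 0, seed = 1L) {
  if (dt <= 0 || tMax <= 0) stop("dt and tMax must be positive")
  if (k0 <= 0) stop("k0 must be positive")
  if (is.finite(oTrue) && oTrue < 1) stop("oTrue must be >= 1 (or Inf)")
  if (growthNoiseCV < 0 || growthNoiseCV >= 1) {
    stop("growthNoiseCV must lie in [0, 1)")
  }
  set.seed(as.integer(seed))

  cThresh <- C0 / oTrue # 0 when oTrue = Inf
  sampleRate <- function(n) {
    if (growthNoiseCV == 0) {
      rep(k0, n)
    } else {
      shape <- 1 / growthNoiseCV^2
      k0 * stats::rgamma(n, shape = shape, scale = 1 / shape)
    }
  }
  sampleFrac <- function(n) {
    if (divisionAsymmetryCV == 0) {
      rep(0.5, n)
    } else {
      a <- (1 / divisionAsymmetryCV^2 - 1) / 2
      stats::rbeta(n, a, a)
    }
  }

  n0 <- as.integer(nProgenitors)
  state <- data.frame(
    id = seq_len(n0), parent = NA_integer_,
    area = rep(initialArea, n0), protein = rep(C0 * initialArea, n0),
    rate = sampleRate(n0), arrested = FALSE
  )
  nextId <- n0 + 1L
  times <- seq(0, tMax, by = dt)
  rec <- vector("list", length(times))
  arrestTimes <- numeric(0)

  checkArrest <- function(state, tNow) {
    conc <- state$protein / state$area
    hit <- !state$arrested & conc <= cThresh * (1 + 1e-9)
    if (any(hit)) {
      state$arrested[hit] <- TRUE
      arrestTimes <<- c(arrestTimes, rep(tNow, sum(hit)))
    }
    state
  }

  state <- checkArrest(state, 0)
  rec[[1]] <- data.frame(
    cell_id = state$id, parent_id = state$parent, time_h = 0,
    area_um2 = state$area, fluor_au = state$protein
  )

  for (i in seq_along(times)[-1]) {
    tNow <- times[i]
    ## growth over (t - dt, t]
    eff <- ifelse(state$arrested, arrestRate, state$rate)
    if (is.finite(hillExponent) && cThresh > 0) {
      conc <- state$protein / state$area
      hill <- conc^hillExponent / (conc^hillExponent + cThresh^hillExponent)
      eff <- ifelse(state$arrested, arrestRate, state$rate * hill)
    }
    grow <- exp(eff * dt)
    state$area <- state$area * grow
    if (synthesisRate > 0) {
      state$protein <- state$protein + synthesisRate * state$area * dt
    }
    ## divisions: record mother at tNow, replace by two daughters also at tNow
    div <- which(state$area >= doublingArea)
    rows <- data.frame(
      cell_id = state$id, parent_id = state$parent, time_h = tNow,
      area_um2 = state$area, fluor_au = state$protein
    )
    if (length(div)) {
      frac <- sampleFrac(length(div))
      kids <- vector("list", length(div))
      for (j in seq_along(div)) {
        m <- div[j]
        a1 <- state$area[m] * frac[j]
        a2 <- state$area[m] - a1
        p1 <- state$protein[m] * frac[j]
        p2 <- state$protein[m] - p1
        ids <- c(nextId, nextId + 1L)
        nextId <- nextId + 2L
        kids[[j]] <- data.frame(
          id = ids, parent = state$id[m], area = c(a1, a2),
          protein = c(p1, p2), rate = sampleRate(2L),
          arrested = state$arrested[m]
        )
      }
      kids <- do.call(rbind, kids)
      rows <- rbind(rows, data.frame(
        cell_id = kids$id, parent_id = kids$parent, time_h = tNow,
        area_um2 = kids$area, fluor_au = kids$protein
      ))
      state <- rbind(state[-div, , drop = FALSE], kids)
    }
    state <- checkArrest(state, tNow)
    rec[[i]] <- rows
  }

  tracks <- do.call(rbind, rec)
  tracks <- tracks[order(tracks$cell_id, tracks$time_h), ]
  rownames(tracks) <- NULL
  new("LineageTree",
    tracks = tracks, progenitorIds = seq_len(n0),
    metadata = list(
      k0 = k0, oTrue = oTrue, C0 = C0, doublingArea = doublingArea,
      initialArea = initialArea, dt = dt, tMax = tMax,
      growthNoiseCV = growthNoiseCV,
      divisionAsymmetryCV = divisionAsymmetryCV,
      arrestRate = arrestRate, hillExponent = hillExponent,
      synthesisRate = synthesisRate, seed = as.integer(seed),
      arrestTimes = arrestTimes
    )
  )
}

#' Simulate a TFNseq knockout-depletion library time course
#'
#' Generates mapped-read counts for a poly-clonal transposon knockout
#' library sampled at timed fractions. Each mutant i carries a log relative
#' abundance g_i(t): 0 for the no-effect class; -s_i * t (an immediate
#' growth-rate deficit s_i) for the sufficient class; 0 up to the arrest
#' time T_i then -k0 * (t - T_i) for the overabundant class (the mutant
#' stops growing while the library continues at k0, so its relative
#' abundance decays at the wild-type rate). Counts at each fraction are a
#' multinomial draw of the configured depth over expected shares
#' proportional to exp(g_i(t)).
#'
#' @param nGenesPerClass named integer vector with entries \code{no_effect},
#'   \code{sufficient}, \code{overabundant}.
#' @param sampleTimes fraction collection times (h), strictly increasing.
#' @param depth reads per fraction.
#' @param k0 wild-type growth rate (1/h).
#' @param sufficiencySlopeRange range of growth-rate deficits s_i (1/h) for
#'   the sufficient class (drawn uniformly).
#' @param overabundanceRange range of true log10 overabundance for the
#'   overabundant class (drawn uniformly); arrest times are
#'   \code{T_i = log(10) * log10o_i / k0}.
#' @param log10o optional explicit vector of true log10 overabundances for
#'   the overabundant class (overrides \code{overabundanceRange}).
#' @param seed integer random seed.
#' @return a \linkS4class{TfnseqExperiment} whose \code{rowData} is the
#'   truth table (\code{class}, \code{slope}, \code{arrest_time_h},
#'   \code{log10_o}).
#' @examples
#' se <- simulateTfnseqLibrary(
#'   nGenesPerClass = c(no_effect = 5, sufficient = 5, overabundant = 5),
#'   depth = 1e4, seed = 7
#' )
#' colSums(SummarizedExperiment::assay(se)) # == depth in every fraction
#' @export
simulateTfnseqLibrary <- function(nGenesPerClass = c(
                                    no_effect = 100L, sufficient = 100L,
                                    overabundant = 100L
                                  ),
                                  sampleTimes = seq(0, 24, by = 2),
                                  depth = 1e5, k0 = log(2),
                                  sufficiencySlopeRange = c(0.2, 0.7),
                                  overabundanceRange = c(0.5, 2.5),
                                  log10o = NULL, seed = 1L) {
  need <- c("no_effect", "sufficient", "overabundant")
  if (!all(need %in% names(nGenesPerClass))) {
    stop("nGenesPerClass needs entries: ", paste(need, collapse = ", "))
  }
  n <- vapply(need, function(k) as.integer(nGenesPerClass[[k]]), integer(1))
  if (sum(n) == 0L) stop("empty library: all class counts are zero")
  if (any(diff(sampleTimes) <= 0)) {
    stop("sampleTimes must be strictly increasing")
  }
  if (depth <= 0) stop("depth must be positive")
  if (any(overabundanceRange <= 0)) {
    stop("overabundanceRange values must be positive")
  }
  set.seed(as.integer(seed))

  cls <- rep(need, times = n)
  nTot <- sum(n)
  slope <- rep(NA_real_, nTot)
  arrest <- rep(NA_real_, nTot)
  l10o <- rep(NA_real_, nTot)

  iSuf <- which(cls == "sufficient")
  slope[iSuf] <- stats::runif(
    length(iSuf), sufficiencySlopeRange[1], sufficiencySlopeRange[2]
  )
  l10o[iSuf] <- 0
  iOve <- which(cls == "overabundant")
  if (is.null(log10o)) {
    l10o[iOve] <- stats::runif(
      length(iOve), overabundanceRange[1], overabundanceRange[2]
    )
  } else {
    if (length(log10o) != length(iOve)) {
      stop("log10o must have one value per overabundant gene")
    }
    l10o[iOve] <- log10o
  }
  arrest[iOve] <- log(10) * l10o[iOve] / k0
  slope[iOve] <- k0

  ## log relative growth of each mutant at each time
  g <- matrix(0, nTot, length(sampleTimes))
  for (j in seq_along(sampleTimes)) {
    t <- sampleTimes[j]
    g[iSuf, j] <- -slope[iSuf] * t
    g[iOve, j] <- -k0 * pmax(0, t - arrest[iOve])
  }
  counts <- matrix(0L, nTot, length(sampleTimes))
  for (j in seq_along(sampleTimes)) {
    p <- exp(g[, j] - max(g[, j]))
    counts[, j] <- stats::rmultinom(1, size = depth, prob = p / sum(p))[, 1]
  }
  ids <- sprintf("gene_%04d", seq_len(nTot))
  rownames(counts) <- ids
  truth <- S4Vectors::DataFrame(
    class = cls, slope = slope, arrest_time_h = arrest, log10_o = l10o,
    row.names = ids
  )
  TfnseqExperiment(counts, sampleTimes,
    rowData = truth,
    metadata = list(
      depth = depth, k0 = k0, seed = as.integer(seed)
    )
  )
}

#' Simulate an RNA-seq count table from message numbers
#'
#' Draws per-gene mapped-read counts as a multinomial over read shares
#' proportional to the message number (transcripts per gene per cell cycle),
#' optionally weighted by gene length (longer transcripts yield more reads
#' in a full-length protocol). It is the sampling inverse of
#' [messageNumberFromCounts()].
#'
#' @param messageNumbers named non-negative numeric vector of per-gene
#'   message numbers.
#' @param depth total mapped reads.
#' @param lengths optional per-gene lengths (bp) for length weighting.
#' @param seed integer random seed.
#' @return \code{data.frame} with \code{gene_id}, \code{count} and, when
#'   provided, \code{length_bp}.
#' @examples
#' simulateRnaseq(c(dnaA = 30, dnaN = 49), depth = 1000, seed = 1)
#' @export
simulateRnaseq <- function(messageNumbers, depth = 1e6, lengths = NULL,
                           seed = 1L) {
  if (any(messageNumbers < 0)) stop("message numbers must be >= 0")
  if (all(messageNumbers == 0)) stop("all message numbers are zero")
  if (depth <= 0) stop("depth must be positive")
  set.seed(as.integer(seed))
  w <- messageNumbers
  if (!is.null(lengths)) {
    if (length(lengths) != length(w)) stop("lengths must match genes")
    w <- w * lengths
  }
  cnt <- stats::rmultinom(1, size = depth, prob = w / sum(w))[, 1]
  ids <- names(messageNumbers)
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_along(messageNumbers))
  out <- data.frame(gene_id = ids, count = as.integer(cnt))
  if (!is.null(lengths)) out$length_bp <- lengths
  out
}

#' Simulate a paper-like genome for the end-to-end pipeline
#'
#' Builds a mixed knockout library (essential genes split between the
#' sufficient and overabundant classes; non-essential genes mostly
#' no-effect with a minority of mild growth defects), assigns each gene a
#' message number, and draws overabundances for the overabundant class near
#' the RLTO optimality curve evaluated at the gene's message number (with
#' lognormal scatter). Returns the TFNseq experiment, an RNA-seq count
#' table, an essentiality annotation, and the per-gene truth.
#'
#' @param nEssential,nNonessential gene counts.
#' @param fracSufficient fraction of essential genes in the sufficient
#'   class.
#' @param fracNoEffectNoness fraction of non-essential genes with no effect.
#' @param epsilon RLTO relative load parameter used for the generating
#'   curve.
#' @param scatterSD lognormal scatter (log10 units) of true overabundance
#'   about the RLTO curve.
#' @param sampleTimes,depth,k0 passed to [simulateTfnseqLibrary()].
#' @param rnaseqDepth total RNA-seq reads.
#' @param totalMessages total transcripts per cell cycle used to scale
#'   message numbers.
#' @param seed integer random seed.
#' @return list with elements \code{tfnseq} (\linkS4class{TfnseqExperiment}
#'   with truth in \code{rowData}), \code{rnaseq} (count table),
#'   \code{annotation} (\code{gene_id}, \code{essential}), \code{truth}
#'   (per-gene \code{class}, \code{log10_o}, \code{mu_m}) and
#'   \code{totalMessages}.
#' @export
simulateGenome <- function(nEssential = 300L, nNonessential = 300L,
                           fracSufficient = 0.31,
                           fracNoEffectNoness = 0.9,
                           epsilon = 1e-3, scatterSD = 0.25,
                           sampleTimes = seq(0, 24, by = 2), depth = 1e5,
                           k0 = log(2), rnaseqDepth = 2e6,
                           totalMessages = 2e4, seed = 1L) {
  set.seed(as.integer(seed))
  nSuf <- round(nEssential * fracSufficient)
  nOve <- nEssential - nSuf
  nNoe <- round(nNonessential * fracNoEffectNoness)
  nMild <- nNonessential - nNoe

  ## message numbers: overabundant (low-expression) essential genes,
  ## sufficient (high-expression) essential genes, broad non-essential;
  ## scaled so the genome totals `totalMessages` transcripts per cycle
  muOve <- 10^stats::rnorm(nOve, mean = 0.9, sd = 0.6)
  muSuf <- 10^stats::rnorm(nSuf, mean = 2.0, sd = 0.5)
  muNon <- 10^stats::rnorm(nNonessential, mean = 1.5, sd = 0.8)
  sc <- totalMessages / (sum(muOve) + sum(muSuf) + sum(muNon))
  muOve <- muOve * sc
  muSuf <- muSuf * sc
  muNon <- muNon * sc

  ## true overabundance near the RLTO curve at each gene's message number
  curve <- vapply(muOve, function(m) {
    log10(optimalOverabundance(RltoParams(m, epsilon = epsilon))$o_star)
  }, numeric(1))
  l10o <- curve + stats::rnorm(nOve, sd = scatterSD)
  l10o <- pmin(pmax(l10o, 0.5), 2.5) # keep arrest inside the time course

  ## mild-defect non-essential genes reuse the sufficiency (slope) model
  se <- simulateTfnseqLibrary(
    nGenesPerClass = c(
      no_effect = nNoe + 0L, sufficient = nSuf + nMild,
      overabundant = nOve
    ),
    sampleTimes = sampleTimes, depth = depth, k0 = k0,
    sufficiencySlopeRange = c(0.2, 0.7),
    log10o = l10o, seed = sample.int(2^31 - 1, 1)
  )
  ## gene order in the library: no_effect, sufficient (ess then mild), over
  essential <- c(
    rep(FALSE, nNoe), rep(TRUE, nSuf), rep(FALSE, nMild), rep(TRUE, nOve)
  )
  mu <- c(
    muNon[seq_len(nNoe)], muSuf,
    muNon[nNoe + seq_len(nMild)], muOve
  )
  ids <- rownames(se)
  truth <- as.data.frame(SummarizedExperiment::rowData(se))
  truth$gene_id <- ids
  truth$essential <- essential
  truth$mu_m <- mu
  rownames(truth) <- NULL
  SummarizedExperiment::rowData(se)$essential <- essential
  SummarizedExperiment::rowData(se)$mu_m <- mu

  names(mu) <- ids
  rna <- simulateRnaseq(mu,
    depth = rnaseqDepth,
    seed = sample.int(2^31 - 1, 1)
  )
  list(
    tfnseq = se, rnaseq = rna,
    annotation = data.frame(gene_id = ids, essential = as.integer(essential)),
    truth = truth[, c(
      "gene_id", "essential", "class", "slope", "arrest_time_h",
      "log10_o", "mu_m"
    )],
    totalMessages = totalMessages
  )
}
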