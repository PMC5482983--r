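#' Default synthetic-landscape configuration
#'
#' Returns the configuration of the seed-deterministic synthetic landscape
#' used throughout the package: a small two-chromosome genome carrying five
#' transcription-factor peak sets with the statistical structure the
#' downstream analyses are designed to detect — Mb-scale alternating
#' gene-rich/gene-poor domains, a densely clustered factor confined to each
#' domain type (ZIC2-like in gene-rich, POU3F1-like in gene-poor), three
#' dispersed factors, planted pairwise co-binding, histone-mark intervals
#' covering a set fraction of co-bound peaks, and a two-condition expression
#' model in which proximity to signature-marked co-bound regions biases
#' genes toward downregulation.
#'
#' All fields can be overridden via \code{...} (top-level names replace the
#' corresponding defaults wholesale).
#'
#' @param seed Integer RNG seed; equal (config, seed) gives byte-identical
#'   artifacts.
#' @param ... Named top-level overrides (\code{genome}, \code{factors},
#'   \code{co_binding}, \code{genes}, \code{signature}, \code{expression},
#'   \code{domain_period}).
#' @return List of class \code{landscape_config}.
#' @export
landscape_config <- function(seed = 1L, ...) {
  cfg <- list(
    genome = list(chroms = c("chr1", "chr2"), lengths = c(2e7, 2e7)),
    # alternating gene-rich / gene-poor blocks of this length, rich first
    domain_period = 1e6,
    factors = list(
      ZIC2 = list(n_peaks = 1500, width_median = 600, width_sigma = 0.6,
                  placement = "clustered-rich", children_mean = 6,
                  child_spread = 2000),
      OTX2 = list(n_peaks = 1500, width_median = 400, width_sigma = 0.5,
                  placement = "uniform"),
      SOX2 = list(n_peaks = 1500, width_median = 400, width_sigma = 0.5,
                  placement = "uniform"),
      POU5F1 = list(n_peaks = 1500, width_median = 400, width_sigma = 0.5,
                    placement = "uniform"),
      POU3F1 = list(n_peaks = 1500, width_median = 600, width_sigma = 0.6,
                    placement = "clustered-poor", children_mean = 6,
                    child_spread = 2000)
    ),
    # ordered pairs: fraction p of a's peaks re-centred inside a b peak
    co_binding = list(
      list(a = "OTX2", b = "ZIC2", p = 0.5),
      list(a = "POU5F1", b = "POU3F1", p = 0.4),
      list(a = "SOX2", b = "POU3F1", p = 0.15)
    ),
    genes = list(n_genes = 5000, rich_poor_ratio = 4, tf_fraction = 0.2),
    # signature mark intervals coincide with the marked peak span (pad 0):
    # keeps the planted marked fraction q an exact recovery target, since
    # padded marks would bleed onto adjacent unmarked peaks of clustered
    # factors
    signature = list(pair = c("ZIC2", "OTX2"), q = 0.4,
                     pad = c(H3K4me1 = 0, H3K27ac = 0),
                     n_background = 300, background_width_median = 1000),
    expression = list(
      baseline_meanlog = log(100), baseline_sdlog = 1,
      fold = 4, noise_sdlog = 0.05,
      p_down = c(background = 0.33, proximal = 0.43, proximal_tf = 0.59),
      p_up = c(background = 0.30, proximal = 0.21, proximal_tf = 0.15),
      conditions = "somatic"
    ),
    seed = as.integer(seed)
  )
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  class(cfg) <- "landscape_config"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  if (any(cfg$genome$lengths < 1)) stop("chromosome lengths must be >= 1")
  if (cfg$domain_period > min(cfg$genome$lengths)) {
    stop("domain_period exceeds the shortest chromosome")
  }
  for (f in names(cfg$factors)) {
    sp <- cfg$factors[[f]]
    if (sp$n_peaks < 0) stop("n_peaks must be >= 0 (factor ", f, ")")
    if (!sp$placement %in% c("clustered-rich", "clustered-poor", "uniform")) {
      stop("unknown placement mode for factor ", f)
    }
  }
  for (cb in cfg$co_binding) {
    if (cb$p < 0 || cb$p > 1) stop("co-binding fraction outside [0,1]")
    if (!all(c(cb$a, cb$b) %in% names(cfg$factors))) {
      stop("co-binding pair references unknown factor")
    }
  }
  q <- cfg$signature$q
  if (q < 0 || q > 1) stop("signature fraction q outside [0,1]")
  ex <- cfg$expression
  if (any(ex$p_down < 0) || any(ex$p_up < 0) ||
      any(ex$p_down + ex$p_up > 1)) {
    stop("expression probabilities invalid: need p_down, p_up >= 0 and ",
         "p_down + p_up <= 1 per gene group")
  }
  invisible(cfg)
}

#' Alternating domain blocks of a genome
#'
#' Deterministic alternation: each chromosome is split from coordinate 0
#' into consecutive blocks of \code{period} bp (trailing partial block
#' kept), labelled gene-rich / gene-poor alternately starting rich.
#'
#' @param genome A \code{Seqinfo}.
#' @param period Block length in bp.
#' @return data.frame: \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open), \code{type} ("rich"/"poor").
#' @export
domain_blocks <- function(genome, period) {
  lens <- .chrom_lengths(genome)
  rows <- lapply(names(lens), function(ch) {
    starts <- seq(0, lens[[ch]] - 1, by = period)
    ends <- pmin(starts + period, lens[[ch]])
    data.frame(chrom = ch, start = starts, end = ends,
               type = rep_len(c("rich", "poor"), length(starts)))
  })
  do.call(rbind, rows)
}

## internal: n positions sampled from blocks, block chosen prop. to weight
.sample_block_positions <- function(n, blocks, weights = NULL) {
  w <- blocks$end - blocks$start
  if (!is.null(weights)) w <- w * weights
  bi <- sample.int(nrow(blocks), n, replace = TRUE, prob = w)
  span <- blocks$end[bi] - blocks$start[bi]
  list(chrom = blocks$chrom[bi],
       pos = blocks$start[bi] + floor(stats::runif(n) * span))
}

## internal: intervals of width w centred at pos, shifted to fit [0, L)
.centre_intervals <- function(chrom, pos, w, lens) {
  L <- lens[chrom]
  start <- pos - w %/% 2
  end <- start + w
  shift_l <- pmax(0, -start)
  start <- start + shift_l; end <- end + shift_l
  shift_r <- pmax(0, end - L)
  start <- start - shift_r; end <- end - shift_r
  start <- pmax(start, 0)  # width > L safeguard (never under sane configs)
  list(start = start, end = end)
}

## internal: iterative within-set overlap resolution, count-conserving.
## resample(k, w): fresh placements for k non-planted peaks of widths w;
## replant(k, w): fresh planted placements. Moves the non-planted member of
## a conflicting pair when possible.
.resolve_overlaps <- function(chrom, start, end, planted,
                              resample, replant, max_iter = 400L) {
  n <- length(start)
  for (it in seq_len(max_iter)) {
    ord <- order(chrom, start, end)
    oc <- chrom[ord]; os <- start[ord]; oe <- end[ord]
    bad <- which(oc[-1] == oc[-n] & os[-1] < oe[-n])
    if (length(bad) == 0L) {
      return(list(chrom = chrom, start = start, end = end))
    }
    first <- ord[bad]; second <- ord[bad + 1L]
    move <- ifelse(planted[second] & !planted[first], first, second)
    move <- unique(move)
    np <- move[!planted[move]]
    pl <- move[planted[move]]
    if (length(np)) {
      new <- resample(length(np), end[np] - start[np])
      chrom[np] <- new$chrom; start[np] <- new$start; end[np] <- new$end
    }
    if (length(pl)) {
      new <- replant(length(pl), end[pl] - start[pl])
      chrom[pl] <- new$chrom; start[pl] <- new$start; end[pl] <- new$end
    }
  }
  stop("capacity error: could not place peaks without same-set overlap ",
       "after ", max_iter, " resampling rounds")
}

#' Generate a synthetic peak landscape
#'
#' Generates, under one RNG seed, per-factor peak sets, a gene annotation
#' and histone-mark interval sets with planted structure (see
#' \code{\link{landscape_config}}): dispersed factors by uniform placement;
#' clustered factors by a parent-child (Neyman-Scott-style) process
#' restricted to their domain type; for each configured ordered pair (a, b)
#' a fraction p of a's peaks re-centred to a uniform position inside a
#' randomly chosen b peak (guaranteeing >= 1 bp overlap, so p is the
#' planted expected overlap fraction); within-set overlaps resolved by
#' rejection resampling (a capacity error is raised rather than silently
#' truncating); gene TSSs placed with the configured rich:poor density
#' ratio; and histone-mark intervals covering a simple-random q-fraction of
#' the designated pair's co-bound peaks plus uniform background intervals
#' per mark.
#'
#' @param config A \code{\link{landscape_config}}.
#' @return List: \code{genome} (Seqinfo), \code{peaks} (named list of peak
#'   sets), \code{annotation} (\code{\link{gene_annotation}}), \code{marks}
#'   (named list: H3K4me1, H3K27ac, H3K27me3), \code{truth} (planted
#'   structure: per-pair planted counts, marked co-bound regions),
#'   \code{config}.
#' @export
generate_landscape <- function(config) {
  .validate_config(config)
  genome <- genome_layout(config$genome$chroms, config$genome$lengths)
  lens <- .chrom_lengths(genome)
  blocks <- domain_blocks(genome, config$domain_period)
  chrom_blocks <- data.frame(chrom = names(lens), start = 0, end = lens,
                             type = "all")

  withr::with_seed(config$seed, {
    raw <- list()
    for (f in names(config$factors)) {
      sp <- config$factors[[f]]
      n <- sp$n_peaks
      if (n == 0L) {
        raw[[f]] <- list(chrom = character(), start = numeric(),
                         end = numeric(), planted = logical())
        next
      }
      widths <- pmax(round(stats::rlnorm(n, log(sp$width_median),
                                         sp$width_sigma)), 20)
      if (sp$placement == "uniform") {
        resample <- function(k, w) {
          p <- .sample_block_positions(k, chrom_blocks)
          c(list(chrom = p$chrom), .centre_intervals(p$chrom, p$pos, w, lens))
        }
      } else {
        type <- if (sp$placement == "clustered-rich") "rich" else "poor"
        home <- blocks[blocks$type == type, , drop = FALSE]
        n_parents <- max(1L, round(n / sp$children_mean))
        par <- .sample_block_positions(n_parents, home)
        resample <- function(k, w) {
          pi <- sample.int(n_parents, k, replace = TRUE)
          pos <- par$pos[pi] + round(stats::rnorm(k, 0, sp$child_spread))
          ch <- par$chrom[pi]
          pos <- pmin(pmax(pos, 0), lens[ch] - 1)
          c(list(chrom = ch), .centre_intervals(ch, pos, w, lens))
        }
      }
      init <- resample(n, widths)
      res <- .resolve_overlaps(init$chrom, init$start, init$end,
                               planted = rep(FALSE, n),
                               resample = resample, replant = resample)
      raw[[f]] <- c(res, list(planted = rep(FALSE, n)))
    }

    # plant co-binding: re-centre a fraction of a's peaks inside b peaks
    planted_k <- list()
    for (cb in config$co_binding) {
      a <- cb$a; b <- cb$b
      n_a <- length(raw[[a]]$start)
      n_b <- length(raw[[b]]$start)
      k <- round(cb$p * n_a)
      planted_k[[paste(a, b, sep = "->")]] <- k
      if (k == 0L || n_b == 0L) next
      idx <- sample.int(n_a, k)
      bset <- raw[[b]]
      replant <- function(k2, w) {
        j <- sample.int(n_b, k2, replace = TRUE)
        mid <- bset$start[j] +
          floor(stats::runif(k2) * (bset$end[j] - bset$start[j]))
        ch <- bset$chrom[j]
        c(list(chrom = ch), .centre_intervals(ch, mid, w, lens))
      }
      w_idx <- raw[[a]]$end[idx] - raw[[a]]$start[idx]
      new <- replant(k, w_idx)
      raw[[a]]$chrom[idx] <- new$chrom
      raw[[a]]$start[idx] <- new$start
      raw[[a]]$end[idx] <- new$end
      raw[[a]]$planted[idx] <- TRUE
      sp <- config$factors[[a]]
      if (sp$placement == "uniform") {
        resample <- function(k2, w) {
          p <- .sample_block_positions(k2, chrom_blocks)
          c(list(chrom = p$chrom), .centre_intervals(p$chrom, p$pos, w, lens))
        }
      } else {
        type <- if (sp$placement == "clustered-rich") "rich" else "poor"
        home <- blocks[blocks$type == type, , drop = FALSE]
        resample <- function(k2, w) {
          p <- .sample_block_positions(k2, home)
          c(list(chrom = p$chrom), .centre_intervals(p$chrom, p$pos, w, lens))
        }
      }
      res <- .resolve_overlaps(raw[[a]]$chrom, raw[[a]]$start, raw[[a]]$end,
                               planted = raw[[a]]$planted,
                               resample = resample, replant = replant)
      raw[[a]]$chrom <- res$chrom
      raw[[a]]$start <- res$start
      raw[[a]]$end <- res$end
    }

    peaks <- lapply(names(raw), function(f) {
      peak_set(raw[[f]]$chrom, raw[[f]]$start, raw[[f]]$end, genome, f)
    })
    names(peaks) <- names(raw)

    # genes: TSS density ratio rich:poor
    gn <- config$genes
    wts <- ifelse(blocks$type == "rich", gn$rich_poor_ratio, 1)
    gp <- .sample_block_positions(gn$n_genes, blocks, weights = wts)
    ann_df <- data.frame(
      gene_id = sprintf("g%05d", seq_len(gn$n_genes)),
      chrom = gp$chrom,
      tss = gp$pos,
      strand = sample(c("+", "-"), gn$n_genes, replace = TRUE),
      is_tf = stats::runif(gn$n_genes) < gn$tf_fraction
    )
    annotation <- gene_annotation(ann_df, genome)

    # histone marks: signature intervals over a q-fraction of the co-bound
    # peaks of the designated pair, plus uniform background per mark
    sg <- config$signature
    cb_regions <- co_bound(peaks[[sg$pair[1]]], peaks[[sg$pair[2]]])
    n_cb <- length(cb_regions)
    n_marked <- round(sg$q * n_cb)
    marked <- if (n_marked > 0L) {
      sort(cb_regions[sample.int(n_cb, n_marked)])
    } else cb_regions[0]

    make_mark <- function(mark_name, pad) {
      sig_start <- pmax(peak_starts(marked) - pad, 0)
      sig_end <- pmin(peak_ends(marked) + pad,
                      lens[as.character(GenomicRanges::seqnames(marked))])
      nb <- sg$n_background
      bw <- pmax(round(stats::rlnorm(nb, log(sg$background_width_median),
                                     0.3)), 50)
      bp <- .sample_block_positions(nb, chrom_blocks)
      bg <- .centre_intervals(bp$chrom, bp$pos, bw, lens)
      gr <- GenomicRanges::GRanges(
        c(as.character(GenomicRanges::seqnames(marked)), bp$chrom),
        IRanges::IRanges(c(sig_start, bg$start) + 1, c(sig_end, bg$end)),
        seqinfo = genome)
      gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
      S4Vectors::metadata(gr)$factor_label <- mark_name
      gr
    }
    marks <- list(
      H3K4me1 = make_mark("H3K4me1", sg$pad[["H3K4me1"]]),
      H3K27ac = make_mark("H3K27ac", sg$pad[["H3K27ac"]]),
      H3K27me3 = {
        nb <- sg$n_background
        bw <- pmax(round(stats::rlnorm(nb, log(sg$background_width_median),
                                       0.3)), 50)
        bp <- .sample_block_positions(nb, chrom_blocks)
        bg <- .centre_intervals(bp$chrom, bp$pos, bw, lens)
        gr <- GenomicRanges::GRanges(
          bp$chrom, IRanges::IRanges(bg$start + 1, bg$end), seqinfo = genome)
        gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
        S4Vectors::metadata(gr)$factor_label <- "H3K27me3"
        gr
      }
    )

    list(genome = genome, peaks = peaks, annotation = annotation,
         marks = marks,
         truth = list(planted_co_binding = planted_k,
                      n_co_bound = n_cb, n_marked = n_marked,
                      marked_regions = marked),
         config = config)
  })
}

#' Generate a two-condition expression table with planted proximity bias
#'
#' Reference expression is log-normal. Per comparison condition and gene,
#' a shift s is drawn: s = -1 with probability p_down, +1 with p_up, else
#' 0, where the probabilities depend on the gene's group (background /
#' proximal / proximal-TF, innermost group wins); the comparison value is
#' reference * fold^s times multiplicative log-normal noise. With fold = 1
#' the configuration is null: both conditions agree up to noise.
#'
#' @param config A \code{\link{landscape_config}} (expression block and
#'   seed are used; the expression stream is seeded independently of the
#'   landscape stream).
#' @param annotation A \code{\link{gene_annotation}}.
#' @param proximal_ids Gene ids proximal to signature-marked co-bound
#'   regions (must exist in the annotation).
#' @param tf_proximal_ids TF-gene subset of \code{proximal_ids}.
#' @return An \code{\link{expression_table}};
#'   \code{attr(, "planted_group")} records each gene's group and
#'   \code{attr(, "planted_shift")} the drawn shifts (genes x conditions).
#' @export
generate_expression <- function(config, annotation, proximal_ids,
                                tf_proximal_ids = character()) {
  .validate_config(config)
  ex <- config$expression
  ids <- annotation$gene_id
  if (!all(proximal_ids %in% ids)) stop("unknown gene id in proximal_ids")
  if (!all(tf_proximal_ids %in% proximal_ids)) {
    stop("tf_proximal_ids must be a subset of proximal_ids")
  }
  n <- length(ids)
  group <- rep("background", n)
  group[ids %in% proximal_ids] <- "proximal"
  group[ids %in% tf_proximal_ids] <- "proximal_tf"
  pd <- ex$p_down[group]
  pu <- ex$p_up[group]
  withr::with_seed(config$seed + 1L, {
    ref <- stats::rlnorm(n, ex$baseline_meanlog, ex$baseline_sdlog)
    df <- data.frame(gene_id = ids, reference = ref)
    shift <- matrix(0L, n, length(ex$conditions),
                    dimnames = list(ids, ex$conditions))
    for (cc in ex$conditions) {
      u <- stats::runif(n)
      s <- ifelse(u < pd, -1L, ifelse(u < pd + pu, 1L, 0L))
      noise <- exp(stats::rnorm(n, 0, ex$noise_sdlog))
      df[[cc]] <- ref * ex$fold^s * noise
      shift[, cc] <- s
    }
    out <- expression_table(df)
    attr(out, "planted_group") <- stats::setNames(group, ids)
    attr(out, "planted_shift") <- shift
    out
  })
}
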