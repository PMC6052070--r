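# Sterol-domain quantification of lattice snapshots: connected-component
# labeling (the particle-analysis step), relative mean domain size on a
# log scale, and the Welch comparison between systems.

#' Label connected domains of target molecule types
#'
#' Connected-component labeling of the cells whose type belongs to
#' \code{targetTypes}, under 4- or 8-connectivity, with clipped (image
#' style, the default) or periodic boundary. Sizes are in cells (= pixels,
#' since each lattice cell is one molecule).
#'
#' @param state a [LatticeState-class], or a logical matrix marking target
#'   cells directly.
#' @param targetTypes character vector of type names (ignored when a
#'   logical matrix is supplied). Defaults to the sterol types.
#' @param connectivity 4 or 8.
#' @param boundary \code{"clipped"} or \code{"periodic"}.
#' @return a \code{domainLabeling}: list with \code{labels} (integer
#'   matrix, 0 = background), \code{sizes} (cells per domain, by label),
#'   and the parameters used.
#' @export
labelDomains <- function(state, targetTypes = c("CHOL", "D7", "STEROL"),
                         connectivity = 8, boundary = c("clipped",
                                                        "periodic")) {
  boundary <- match.arg(boundary)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (is(state, "LatticeState")) {
    targetTypes <- intersect(targetTypes, moleculeTypes(state))
    if (!length(targetTypes)) stop("no target type present on the lattice")
    mask <- matrix(moleculeTypes(state)[latticeGrid(state)] %in% targetTypes,
                   nrow(latticeGrid(state)))
  } else {
    stopifnot(is.matrix(state), is.logical(state))
    mask <- state
  }
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  periodic <- boundary == "periodic"
  lab <- 0L
  sizes <- integer(0)
  stack <- integer(nr * nc)
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    top <- 1L
    stack[1L] <- start
    labels[start] <- lab
    sz <- 0L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      sz <- sz + 1L
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (periodic) {
          rr <- ((rr - 1L) %% nr) + 1L
          cc <- ((cc - 1L) %% nc) + 1L
        } else if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        idx <- (cc - 1L) * nr + rr
        if (mask[idx] && labels[idx] == 0L) {
          labels[idx] <- lab
          top <- top + 1L
          stack[top] <- idx
        }
      }
    }
    sizes[lab] <- sz
  }
  structure(list(labels = labels, sizes = sizes,
                 targetTypes = targetTypes, connectivity = connectivity,
                 boundary = boundary),
            class = "domainLabeling")
}

#' @export
print.domainLabeling <- function(x, ...) {
  cat(sprintf("domainLabeling: %d domains over %d target cells (connectivity %d, %s boundary)\n",
              length(x$sizes), sum(x$sizes), x$connectivity, x$boundary))
  invisible(x)
}

#' Summary statistics of a domain labeling
#'
#' Mean domain size, total target area, their ratio (the relative mean
#' domain size, which relativizes cluster size between systems of
#' different sterol content) and its natural log (the variance-stabilized
#' quantity the Welch comparison runs on).
#'
#' @param lab a \code{domainLabeling} from [labelDomains()] with at least
#'   one domain.
#' @return list with \code{nDomains}, \code{meanSize},
#'   \code{totalTargetArea}, \code{relativeMeanSize},
#'   \code{logRelativeMeanSize}.
#' @export
domainStats <- function(lab) {
  if (!length(lab$sizes))
    stop("no domains: statistics undefined for an empty labeling")
  meanSize <- mean(lab$sizes)
  total <- sum(lab$sizes)
  rel <- meanSize / total
  list(nDomains = length(lab$sizes), meanSize = meanSize,
       totalTargetArea = total, relativeMeanSize = rel,
       logRelativeMeanSize = log(rel))
}

#' Welch's two-sample t test
#'
#' Unequal-variance two-sample comparison (Welch statistic,
#' Welch-Satterthwaite degrees of freedom, two-sided p), delegated to
#' [stats::t.test()]. The degenerate case of two zero-variance groups with
#' equal means returns t = 0, p = 1 by convention.
#'
#' @param groupA,groupB numeric vectors with >= 2 values each.
#' @return an object of class \code{htest}.
#' @export
welchTest <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  if (!all(is.finite(c(groupA, groupB))))
    stop("groups must be finite")
  if (var(groupA) == 0 && var(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) {
      out <- list(statistic = c(t = 0),
                  parameter = c(df = length(groupA) + length(groupB) - 2),
                  p.value = 1,
                  estimate = c(`mean of x` = mean(groupA),
                               `mean of y` = mean(groupB)),
                  alternative = "two.sided",
                  method = "Welch Two Sample t-test",
                  data.name = "groupA and groupB")
      class(out) <- "htest"
      return(out)
    }
    stop("both groups have zero variance with different means; t undefined")
  }
  stats::t.test(groupA, groupB, var.equal = FALSE)
}

#' Compare sterol-domain statistics between two simulated systems
#'
#' Applies [welchTest()] to the per-replicate log relative mean domain
#' sizes of two systems and assembles a tidy per-replicate summary table.
#'
#' @param statsA,statsB lists of [domainStats()] results (>= 2 replicates
#'   each).
#' @param labels length-2 character vector naming the systems.
#' @param csvFile optional path; if given, the summary table is written
#'   as CSV.
#' @return a \code{systemComparison}: list with \code{test} (htest),
#'   \code{summary} (data.frame), \code{labels}.
#' @export
compareSystems <- function(statsA, statsB, labels = c("A", "B"),
                           csvFile = NULL) {
  pull <- function(stats, label) {
    do.call(rbind, lapply(seq_along(stats), function(i) {
      s <- stats[[i]]
      data.frame(system = label, replicate = i, nDomains = s$nDomains,
                 meanSize = s$meanSize,
                 totalTargetArea = s$totalTargetArea,
                 relativeMeanSize = s$relativeMeanSize,
                 logRelativeMeanSize = s$logRelativeMeanSize)
    }))
  }
  tab <- rbind(pull(statsA, labels[1]), pull(statsB, labels[2]))
  test <- welchTest(
    vapply(statsA, `[[`, numeric(1), "logRelativeMeanSize"),
    vapply(statsB, `[[`, numeric(1), "logRelativeMeanSize"))
  if (!is.null(csvFile)) write.csv(tab, csvFile, row.names = FALSE)
  structure(list(test = test, summary = tab, labels = labels),
            class = "systemComparison")
}

#' @export
print.systemComparison <- function(x, ...) {
  m <- tapply(x$summary$logRelativeMeanSize, x$summary$system, mean)
  cat(sprintf("systemComparison %s vs %s (log relative mean domain size)\n",
              x$labels[1], x$labels[2]))
  cat(sprintf("  means: %s = %.3f, %s = %.3f\n", x$labels[1],
              m[[x$labels[1]]], x$labels[2], m[[x$labels[2]]]))
  cat(sprintf("  Welch t = %.4f, df = %.4f, p = %.4g\n",
              unname(x$test$statistic), unname(x$test$parameter),
              x$test$p.value))
  invisible(x)
}
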