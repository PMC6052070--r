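# Shared helpers: oriented fixture molecules (cached per session) and tiny
# hand-built molecules used across test files.

orientedFixture <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      m <- fixtureMolecule(name)
      cache[[name]] <<- transformMolecule(m, orientAtInterface(m))
    }
    cache[[name]]
  }
})

# a molecule from a bare atom table using element defaults
quickMol <- function(element, x, y = 0, z = 0, charge = NULL, ...) {
  df <- data.frame(name = paste0(element, seq_along(x)), element = element,
                   x = x, y = y, z = z)
  if (!is.null(charge)) df$charge <- charge
  readStructure(df, ...)
}

# single-atom "molecules" for docking oracles
singleAtom <- function(element = "C", charge = 0) {
  quickMol(element, x = 0, charge = charge)
}

# independent flood-fill oracle for connected-component labeling
floodFillOracle <- function(mask, connectivity, boundary) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (boundary == "periodic") {
          r <- ((r - 1) %% nr) + 1; c <- ((c - 1) %% nc) + 1
        } else if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# normalize a labeling to a canonical form for comparison
canonicalLabels <- function(lab) {
  v <- as.vector(lab)
  first <- !duplicated(v) & v != 0
  map <- integer(max(v, 1))
  map[v[first]] <- seq_len(sum(first))
  out <- v
  out[v != 0] <- map[v[v != 0]]
  matrix(out, nrow(lab))
}
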