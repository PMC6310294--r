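#' Pedigree construction and validation
#'
#' Builds a validated, topologically sorted pedigree from raw parentage
#' triples. Unknown parents (coded `NA`, `""` or `"0"`) are treated as
#' base-population founders. Parents that are referenced but never listed as
#' animals themselves are added as founder records. The returned order is a
#' deterministic topological sort (every parent precedes all of its
#' offspring), with ties broken by order of first appearance in the input.
#'
#' @param animal,sire,dam character (or coercible) vectors of equal length
#'   giving, per record, the animal identifier and its parents.
#' @return An object of class `pedigree`: a `data.frame` with columns
#'   `animal`, `sire`, `dam` (character; `NA` for unknown parents) in sorted
#'   order, plus integer attribute columns `sire_idx`/`dam_idx` (0 =
#'   unknown) used by the matrix algebra.
#' @examples
#' ped <- validate_pedigree(c("S", "D", "X"), c(NA, NA, "S"), c(NA, NA, "D"))
#' ped$animal
#' @export
validate_pedigree <- function(animal, sire, dam) {
  animal <- normalise_id(animal)
  sire <- normalise_id(sire)
  dam <- normalise_id(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal)) {
    stop("animal, sire and dam must have equal length")
  }
  if (anyNA(animal)) stop("animal identifiers must not be missing")
  if (anyDuplicated(animal)) {
    stop("duplicate animal id: ", animal[duplicated(animal)][1L])
  }
  ## implicit founders: parents never listed as animals
  parents <- unique(c(sire, dam))
  parents <- parents[!is.na(parents)]
  implicit <- setdiff(parents, animal)
  if (length(implicit)) {
    animal <- c(implicit, animal)
    sire <- c(rep(NA_character_, length(implicit)), sire)
    dam <- c(rep(NA_character_, length(implicit)), dam)
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  if (any(!is.na(si) & si == seq_len(n)) || any(!is.na(di) & di == seq_len(n))) {
    bad <- animal[which((!is.na(si) & si == seq_len(n)) |
                          (!is.na(di) & di == seq_len(n)))[1L]]
    stop("pedigree cycle detected involving animal ", bad)
  }
  ## Kahn-style layered topological sort; within a layer keep input order
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[pmax(si, 1L)]) &
      (is.na(di) | placed[pmax(di, 1L)])
    # pmax guard: si/di NA entries are masked by is.na() above
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    ## walk parent pointers inside the unplaced set until an id repeats
    start <- which(!placed)[1L]
    seen <- integer(0)
    cur <- start
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      nxt <- c(si[cur], di[cur])
      nxt <- nxt[!is.na(nxt) & !placed[nxt]]
      cur <- nxt[1L]
    }
    stop("pedigree cycle detected involving animal ", animal[cur])
  }
  ped <- data.frame(
    animal = animal[ord],
    sire = sire[ord],
    dam = dam[ord],
    stringsAsFactors = FALSE
  )
  ped$sire_idx <- match(ped$sire, ped$animal)
  ped$dam_idx <- match(ped$dam, ped$animal)
  ped$sire_idx[is.na(ped$sire_idx)] <- 0L
  ped$dam_idx[is.na(ped$dam_idx)] <- 0L
  class(ped) <- c("pedigree", "data.frame")
  ped
}

normalise_id <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

is_pedigree <- function(x) inherits(x, "pedigree")

assert_pedigree <- function(ped) {
  if (!is_pedigree(ped)) stop("expected a validated pedigree; see validate_pedigree()")
  s <- ped$sire_idx
  d <- ped$dam_idx
  i <- seq_len(nrow(ped))
  if (any(s >= i) || any(d >= i)) {
    stop("pedigree is not topologically sorted; rebuild with validate_pedigree()")
  }
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "animals (",
      sum(x$sire_idx == 0L & x$dam_idx == 0L), "founders )\n")
  print.data.frame(utils::head(as.data.frame(x)[, c("animal", "sire", "dam")], 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Additive (numerator) relationship matrix
#'
#' Computes the dense additive relationship matrix `A` by the tabular
#' method: `a_ii = 1 + 0.5 a_{s(i),d(i)}` and
#' `a_ij = 0.5 (a_{j,s(i)} + a_{j,d(i)})` for `j` earlier in pedigree order,
#' terms with unknown parents dropping out. Diagonal entries are `1 + F_i`
#' where `F_i` is the inbreeding coefficient.
#'
#' @param ped a validated [validate_pedigree()] pedigree.
#' @return A symmetric numeric matrix with dimnames equal to animal ids.
#' @export
relationship_matrix <- function(ped) {
  assert_pedigree(ped)
  n <- nrow(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s[i] > 0L) row <- row + A[j, s[i]]
      if (d[i] > 0L) row <- row + A[j, d[i]]
      row <- 0.5 * row
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Inbreeding coefficients
#'
#' `F_i` is half the additive relationship between the parents of `i`
#' (zero when either parent is unknown). Computed from a tabular
#' relationship matrix restricted to the ancestor sub-pedigree, so the cost
#' is quadratic in the number of parents rather than in pedigree size.
#'
#' @inheritParams relationship_matrix
#' @return Named numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  assert_pedigree(ped)
  n <- nrow(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  f <- numeric(n)
  anc <- sort(unique(c(s[s > 0L], d[d > 0L])))
  if (length(anc)) {
    ## ancestor set is closed under parenthood (parents of parents are parents)
    sub <- ped[anc, , drop = FALSE]
    class(sub) <- c("pedigree", "data.frame")
    sub$sire_idx <- match(ped$sire[anc], sub$animal)
    sub$dam_idx <- match(ped$dam[anc], sub$animal)
    sub$sire_idx[is.na(sub$sire_idx)] <- 0L
    sub$dam_idx[is.na(sub$dam_idx)] <- 0L
    Aanc <- relationship_matrix(sub)
    pos <- match(seq_len(n), anc) # position of each animal inside ancestor set
    both <- which(s > 0L & d > 0L)
    if (length(both)) {
      f[both] <- 0.5 * Aanc[cbind(pos[s[both]], pos[d[both]])]
    }
  }
  names(f) <- ped$animal
  f
}

## Mendelian-sampling variance ratios d_i such that A = T D T' (D = diag(d))
mendelian_variance <- function(ped, f = inbreeding(ped)) {
  s <- ped$sire_idx
  d <- ped$dam_idx
  fs <- fd <- rep(NA_real_, nrow(ped)) # 0 = unknown parent, must not index f
  fs[s > 0L] <- f[s[s > 0L]]
  fd[d > 0L] <- f[d[d > 0L]]
  ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (fs + fd),
         ifelse(s > 0L, 0.75 - 0.25 * fs,
                ifelse(d > 0L, 0.75 - 0.25 * fd, 1)))
}

#' Inverse of the additive relationship matrix
#'
#' Direct sparse construction (Henderson's rules with full accounting for
#' parental inbreeding): writing `A = T D T'` with `T` unit lower triangular
#' and `D` the diagonal of Mendelian-sampling variance ratios,
#' `A^{-1} = (T^{-1})' D^{-1} T^{-1}` is assembled animal by animal.
#'
#' @inheritParams relationship_matrix
#' @return A sparse symmetric [Matrix::Matrix] with attribute `"logdet"`
#'   holding `log det(A) = sum(log d_i)`.
#' @export
relationship_inverse <- function(ped) {
  assert_pedigree(ped)
  n <- nrow(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  dv <- mendelian_variance(ped)
  m <- 1 / dv
  ii <- list(seq_len(n))
  jj <- list(seq_len(n))
  xx <- list(m)
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i
    jj[[k]] <<- j
    xx[[k]] <<- x
  }
  bs <- s > 0L
  bd <- d > 0L
  w <- which(bs)
  if (length(w)) {
    add(w, s[w], -0.5 * m[w])
    add(s[w], w, -0.5 * m[w])
    add(s[w], s[w], 0.25 * m[w])
  }
  w <- which(bd)
  if (length(w)) {
    add(w, d[w], -0.5 * m[w])
    add(d[w], w, -0.5 * m[w])
    add(d[w], d[w], 0.25 * m[w])
  }
  w <- which(bs & bd)
  if (length(w)) {
    add(s[w], d[w], 0.25 * m[w])
    add(d[w], s[w], 0.25 * m[w])
  }
  Ainv <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, n), dimnames = list(ped$animal, ped$animal)
  )
  Ainv <- Matrix::forceSymmetric(Matrix::drop0(Ainv))
  attr(Ainv, "logdet") <- sum(log(dv))
  Ainv
}

#' Read or write a pedigree file
#'
#' Delimited text with header `animal,sire,dam` (comma or tab, auto-detected
#' on read). Unknown parents are written as empty fields; on read, empty,
#' `"0"` and `NA` fields all denote unknown.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a validated pedigree;
#'   `write_pedigree()` returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = c("", "NA"))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(raw))) {
    stop("pedigree file must have columns animal, sire, dam")
  }
  validate_pedigree(raw$animal, raw$sire, raw$dam)
}

#' @rdname read_pedigree
#' @param ped a pedigree to write.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @export
write_pedigree <- function(ped, path, sep = ",") {
  assert_pedigree(ped)
  out <- as.data.frame(ped)[, c("animal", "sire", "dam")]
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
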