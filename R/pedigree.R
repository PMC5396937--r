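#' Pedigree tables
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam`, `sex`
#' (`"M"`/`"F"`), `generation` (integer, founders at 0), and `population`.
#' Founders have both parents `NA`; rows are stored topologically so that
#' every parent precedes its offspring. `as_pedigree()` validates and
#' reorders an arbitrary table into this form.
#'
#' @param x data frame with at least columns id, sire, dam, sex, generation,
#'   population (missing generation/population are filled with defaults).
#' @return An object of class `pedigree_table` (a data frame).
#' @examples
#' ped <- as_pedigree(data.frame(
#'   id = c("f1", "f2", "o1"), sire = c(NA, NA, "f1"),
#'   dam = c(NA, NA, "f2"), sex = c("M", "F", "F"),
#'   generation = c(0, 0, 1), population = "demo"))
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam", "sex")
  if (!all(need %in% names(x)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  x$id <- as.character(x$id)
  x$sire <- as.character(x$sire)
  x$dam <- as.character(x$dam)
  x$sire[x$sire %in% c("", "NA", "0")] <- NA_character_
  x$dam[x$dam %in% c("", "NA", "0")] <- NA_character_
  if (anyDuplicated(x$id)) stop("duplicate pedigree ids: ",
                                x$id[duplicated(x$id)][1])
  x$sex <- toupper(substr(as.character(x$sex), 1, 1))
  if (!all(x$sex %in% c("M", "F")))
    stop("sex must be coded M/F (male/female)")
  if (is.null(x$population)) x$population <- "pop1"
  for (p in c("sire", "dam")) {
    bad <- !is.na(x[[p]]) & !(x[[p]] %in% x$id)
    if (any(bad))
      stop("unknown ", p, " id for individual ", x$id[bad][1],
           ": ", x[[p]][bad][1])
  }
  if (any(!is.na(x$sire) & x$sire == x$id) ||
      any(!is.na(x$dam) & x$dam == x$id))
    stop("individual listed as its own parent")
  ord <- ped_topo_order(x$id, x$sire, x$dam)
  x <- x[ord, , drop = FALSE]
  if (is.null(x$generation)) {
    depth <- integer(nrow(x)); names(depth) <- x$id
    for (i in seq_len(nrow(x))) {
      pd <- c(depth[x$sire[i]], depth[x$dam[i]])
      depth[i] <- if (all(is.na(pd))) 0L else max(pd, na.rm = TRUE) + 1L
    }
    x$generation <- unname(depth)
  }
  x$generation <- as.integer(x$generation)
  rownames(x) <- NULL
  class(x) <- c("pedigree_table", "data.frame")
  x
}

# Kahn topological sort; detects parentage cycles.
ped_topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n); names(idx) <- id
  si <- ifelse(is.na(sire), NA_integer_, idx[sire])
  di <- ifelse(is.na(dam), NA_integer_, idx[dam])
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) stop("cycle detected in pedigree parentage")
  out
}

#' Read / write pedigree CSV
#'
#' Pedigree files are plain CSV with header columns
#' `id,sire,dam,sex,generation,population`; empty sire/dam marks a founder.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a [as_pedigree()] validated pedigree;
#'   `write_pedigree()` returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (nrow(x) == 0L) stop("empty pedigree file: ", path)
  as_pedigree(x)
}

#' @rdname read_pedigree
#' @param ped pedigree table.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree_table"))
  out <- as.data.frame(ped)[, c("id", "sire", "dam", "sex",
                                "generation", "population")]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.pedigree_table <- function(x, ...) {
  cat(sprintf("pedigree: %d members, %d founders, generations %d-%d\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam)),
              min(x$generation), max(x$generation)))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
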