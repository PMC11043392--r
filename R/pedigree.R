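# Pedigree store: append-only parent links for every individual ever born.
# Individuals are identified by dense integer ids in birth order; founders
# carry parent id 0 and act as attachment points ("founder tokens") for the
# coalescent initialisation of standing diversity.

new_pedigree <- function(capacity = 8192L) {
  e <- new.env(parent = emptyenv())
  e$father <- integer(capacity)
  e$mother <- integer(capacity)
  e$sex <- integer(capacity)   # 1 = male, 2 = female
  e$n <- 0L
  class(e) <- "pedigree"
  e
}

ped_add <- function(ped, father, mother, sex) {
  k <- length(father)
  stopifnot(length(mother) == k, length(sex) == k)
  need <- ped$n + k
  if (need > length(ped$father)) {
    cap <- max(2L * length(ped$father), need)
    ped$father <- `length<-`(ped$father, cap)
    ped$mother <- `length<-`(ped$mother, cap)
    ped$sex <- `length<-`(ped$sex, cap)
  }
  ids <- ped$n + seq_len(k)
  ped$father[ids] <- father
  ped$mother[ids] <- mother
  ped$sex[ids] <- sex
  ped$n <- need
  ids
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree>", x$n, "individuals\n")
  invisible(x)
}
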