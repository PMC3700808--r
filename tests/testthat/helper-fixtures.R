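library(dplyr)

# mask with 1-bits over the given closed intervals
make_mask <- function(L, ...) {
  bits <- integer(L)
  for (iv in list(...)) bits[iv[1]:iv[2]] <- 1L
  bits
}

random_mask <- function(L, max_stretches = 4) {
  bits <- integer(L)
  k <- sample(0:max_stretches, 1)
  for (i in seq_len(k)) {
    s <- sample(L, 1)
    e <- min(L, s + sample(0:9, 1))
    bits[s:e] <- 1L
  }
  bits
}

# minimal atom tibble for contact tests
atoms_tbl <- function(chain, resnum, x, y = 0, z = 0, element = "C") {
  tibble(
    chain_id = chain, residue_number = as.integer(resnum),
    insertion_code = "", residue_name = "GLY", atom_name = "CA",
    element = element, x = as.double(x), y = as.double(y), z = as.double(z),
    occupancy = 1
  )
}

# hand-built single-isoform control set with prescribed decoy layouts:
# one missing stretch of `size`, given starts
fake_control_set <- function(L, size, starts) {
  structure(list(mode = "single", L = L, status = 1L, real_sizes = size,
                 sizes = matrix(size, nrow = length(starts)),
                 starts = as.integer(starts), n_controls = length(starts)),
            class = "control_set")
}

# independently coded textbook CMH statistic over an a/b/c/d table set
cmh_oracle <- function(tab, correction = TRUE) {
  num <- 0; den <- 0; suma <- 0
  for (i in seq_len(nrow(tab))) {
    a <- tab$a[i]; b <- tab$b[i]; c <- tab$c[i]; d <- tab$d[i]
    n <- a + b + c + d
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0 || n < 2) next
    suma <- suma + a
    num <- num + (a + b) * (a + c) / n
    den <- den + (a + b) * (c + d) * (a + c) * (b + d) / (n * n * (n - 1))
  }
  if (den == 0) return(NA_real_)
  delta <- abs(suma - num)
  (delta - if (correction && delta >= 0.5) 0.5 else 0)^2 / den
}
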