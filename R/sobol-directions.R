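# Joe-Kuo direction-number table (new-joe-kuo-6), dimensions 2..100.
# Column 1: primitive polynomial (coded integer); remaining columns: initial
# direction numbers m_j (0 = unused beyond the polynomial degree).
.sobol_joe_kuo <- matrix(c(
  3, 1, 0, 0, 0, 0, 0, 0, 0, 0,
  7, 1, 3, 0, 0, 0, 0, 0, 0, 0,
  11, 1, 3, 1, 0, 0, 0, 0, 0, 0,
  13, 1, 1, 1, 0, 0, 0, 0, 0, 0,
  19, 1, 1, 3, 3, 0, 0, 0, 0, 0,
  25, 1, 3, 5, 13, 0, 0, 0, 0, 0,
  37, 1, 1, 5, 5, 17, 0, 0, 0, 0,
  41, 1, 1, 5, 5, 5, 0, 0, 0, 0,
  47, 1, 1, 7, 11, 19, 0, 0, 0, 0,
  55, 1, 1, 5, 1, 1, 0, 0, 0, 0,
  59, 1, 1, 1, 3, 11, 0, 0, 0, 0,
  61, 1, 3, 5, 5, 31, 0, 0, 0, 0,
  67, 1, 3, 3, 9, 7, 49, 0, 0, 0,
  91, 1, 1, 1, 15, 21, 21, 0, 0, 0,
  97, 1, 3, 1, 13, 27, 49, 0, 0, 0,
  103, 1, 1, 1, 15, 7, 5, 0, 0, 0,
  109, 1, 3, 1, 15, 13, 25, 0, 0, 0,
  115, 1, 1, 5, 5, 19, 61, 0, 0, 0,
  131, 1, 3, 7, 11, 23, 15, 103, 0, 0,
  137, 1, 3, 7, 13, 13, 15, 69, 0, 0,
  143, 1, 1, 3, 13, 7, 35, 63, 0, 0,
  145, 1, 3, 5, 9, 1, 25, 53, 0, 0,
  157, 1, 3, 1, 13, 9, 35, 107, 0, 0,
  167, 1, 3, 1, 5, 27, 61, 31, 0, 0,
  171, 1, 1, 5, 11, 19, 41, 61, 0, 0,
  185, 1, 3, 5, 3, 3, 13, 69, 0, 0,
  191, 1, 1, 7, 13, 1, 19, 1, 0, 0,
  193, 1, 3, 7, 5, 13, 19, 59, 0, 0,
  203, 1, 1, 3, 9, 25, 29, 41, 0, 0,
  211, 1, 3, 5, 13, 23, 1, 55, 0, 0,
  213, 1, 3, 7, 3, 13, 59, 17, 0, 0,
  229, 1, 3, 1, 3, 5, 53, 69, 0, 0,
  239, 1, 1, 5, 5, 23, 33, 13, 0, 0,
  241, 1, 1, 7, 7, 1, 61, 123, 0, 0,
  247, 1, 1, 7, 9, 13, 61, 49, 0, 0,
  253, 1, 3, 3, 5, 3, 55, 33, 0, 0,
  285, 1, 3, 1, 15, 31, 13, 49, 245, 0,
  299, 1, 3, 5, 15, 31, 59, 63, 97, 0,
  301, 1, 3, 1, 11, 11, 11, 77, 249, 0,
  333, 1, 3, 1, 11, 27, 43, 71, 9, 0,
  351, 1, 1, 7, 15, 21, 11, 81, 45, 0,
  355, 1, 3, 7, 3, 25, 31, 65, 79, 0,
  357, 1, 3, 1, 1, 19, 11, 3, 205, 0,
  361, 1, 1, 5, 9, 19, 21, 29, 157, 0,
  369, 1, 3, 7, 11, 1, 33, 89, 185, 0,
  391, 1, 3, 3, 3, 15, 9, 79, 71, 0,
  397, 1, 3, 7, 11, 15, 39, 119, 27, 0,
  425, 1, 1, 3, 1, 11, 31, 97, 225, 0,
  451, 1, 1, 1, 3, 23, 43, 57, 177, 0,
  463, 1, 3, 7, 7, 17, 17, 37, 71, 0,
  487, 1, 3, 1, 5, 27, 63, 123, 213, 0,
  501, 1, 1, 3, 5, 11, 43, 53, 133, 0,
  529, 1, 3, 5, 5, 29, 17, 47, 173, 479,
  539, 1, 3, 3, 11, 3, 1, 109, 9, 69,
  545, 1, 1, 1, 5, 17, 39, 23, 5, 343,
  557, 1, 3, 1, 5, 25, 15, 31, 103, 499,
  563, 1, 1, 1, 11, 11, 17, 63, 105, 183,
  601, 1, 1, 5, 11, 9, 29, 97, 231, 363,
  607, 1, 1, 5, 15, 19, 45, 41, 7, 383,
  617, 1, 3, 7, 7, 31, 19, 83, 137, 221,
  623, 1, 1, 1, 3, 23, 15, 111, 223, 83,
  631, 1, 1, 5, 13, 31, 15, 55, 25, 161,
  637, 1, 1, 3, 13, 25, 47, 39, 87, 257,
  647, 1, 1, 1, 11, 21, 53, 125, 249, 293,
  661, 1, 1, 7, 11, 11, 7, 57, 79, 323,
  675, 1, 1, 5, 5, 17, 13, 81, 3, 131,
  677, 1, 1, 7, 13, 23, 7, 65, 251, 475,
  687, 1, 3, 5, 1, 9, 43, 3, 149, 11,
  695, 1, 1, 3, 13, 31, 13, 13, 255, 487,
  701, 1, 3, 3, 1, 5, 63, 89, 91, 127,
  719, 1, 1, 3, 3, 1, 19, 123, 127, 237,
  721, 1, 1, 5, 7, 23, 31, 37, 243, 289,
  731, 1, 1, 5, 11, 17, 53, 117, 183, 491,
  757, 1, 1, 1, 5, 1, 13, 13, 209, 345,
  761, 1, 1, 3, 15, 1, 57, 115, 7, 33,
  787, 1, 3, 1, 11, 7, 43, 81, 207, 175,
  789, 1, 3, 1, 1, 15, 27, 63, 255, 49,
  799, 1, 3, 5, 3, 27, 61, 105, 171, 305,
  803, 1, 1, 5, 3, 1, 3, 57, 249, 149,
  817, 1, 1, 3, 5, 5, 57, 15, 13, 159,
  827, 1, 1, 1, 11, 7, 11, 105, 141, 225,
  847, 1, 3, 3, 5, 27, 59, 121, 101, 271,
  859, 1, 3, 5, 9, 11, 49, 51, 59, 115,
  865, 1, 1, 7, 1, 23, 45, 125, 71, 419,
  875, 1, 1, 3, 5, 23, 5, 105, 109, 75,
  877, 1, 1, 7, 15, 7, 11, 67, 121, 453,
  883, 1, 3, 7, 3, 9, 13, 31, 27, 449,
  895, 1, 3, 1, 15, 19, 39, 39, 89, 15,
  901, 1, 1, 1, 1, 1, 33, 73, 145, 379,
  911, 1, 3, 1, 15, 15, 43, 29, 13, 483,
  949, 1, 1, 7, 3, 19, 27, 85, 131, 431,
  953, 1, 3, 3, 3, 5, 35, 23, 195, 349,
  967, 1, 3, 3, 7, 9, 27, 39, 59, 297,
  971, 1, 1, 3, 9, 11, 17, 13, 241, 157,
  973, 1, 3, 7, 15, 25, 57, 33, 189, 213,
  981, 1, 1, 7, 1, 9, 55, 73, 83, 217,
  985, 1, 3, 3, 13, 19, 27, 23, 113, 249,
  995, 1, 3, 5, 3, 23, 43, 3, 253, 479,
  1001, 1, 1, 5, 5, 11, 5, 45, 117, 217
), ncol = 10L, byrow = TRUE)
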