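/* 'same'-padded stride-1 1D convolution, channels-first, as a sum of
 * offset GEMMs.
 *
 * Activations are channels-first, column-major: a (C x B*L) matrix
 * whose column (b-1)*L + l holds the C channel values of item b at
 * time l.  The weight matrix is (C*K x F) with row (k-1)*C + c the
 * weight of input channel c at tap k.  For each tap k the valid
 * destination range of each item is a contiguous column block, so the
 * whole convolution is K*B dgemm calls with pointer offsets and no
 * materialized im2col buffer; the backward passes accumulate with
 * beta = 1 the same way.  Items are padded independently (taps never
 * cross an item boundary).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/BLAS.h>
#include <string.h>

/* Forward: Out (F x B*L) = sum_k W_k^T A_(shifted k) + bias. */
SEXP C_conv1d_fwd(SEXP A_, SEXP W_, SEXP bias_, SEXP B_, SEXP L_,
                  SEXP K_)
{
    const double *A = REAL(A_);
    const double *W = REAL(W_);
    const double *bias = REAL(bias_);
    const int C = Rf_nrows(A_);
    const int F = Rf_ncols(W_);
    const int B = Rf_asInteger(B_);
    const int L = Rf_asInteger(L_);
    const int K = Rf_asInteger(K_);
    const int CK = C * K;
    const int padL = (K - 1) / 2;
    const R_xlen_t BL = (R_xlen_t) B * L;
    const double one = 1.0;

    SEXP out_ = PROTECT(Rf_allocMatrix(REALSXP, F, (int) BL));
    double *out = REAL(out_);
    for (R_xlen_t r = 0; r < BL; r++)
        memcpy(out + r * F, bias, F * sizeof(double));

    for (int k = 0; k < K; k++) {
        const int sh = k - padL;              /* source = dest + sh */
        const int l0 = sh > 0 ? 0 : -sh;
        const int l1 = sh > 0 ? L - sh : L;
        if (l1 <= l0) continue;
        const int len = l1 - l0;
        for (int b = 0; b < B; b++) {
            const R_xlen_t base = (R_xlen_t) b * L;
            F77_CALL(dgemm)("T", "N", &F, &len, &C, &one,
                            W + (R_xlen_t) k * C, &CK,
                            A + (base + l0 + sh) * C, &C, &one,
                            out + (base + l0) * F, &F
                            FCONE FCONE);
        }
    }
    UNPROTECT(1);
    return out_;
}

/* Data gradient: dA (C x B*L) = sum_k W_k dOut_(shifted -k). */
SEXP C_conv1d_bwd_data(SEXP W_, SEXP dOut_, SEXP B_, SEXP L_, SEXP K_)
{
    const double *W = REAL(W_);
    const double *dOut = REAL(dOut_);
    const int F = Rf_nrows(dOut_);
    const int CK = Rf_nrows(W_);
    const int B = Rf_asInteger(B_);
    const int L = Rf_asInteger(L_);
    const int K = Rf_asInteger(K_);
    const int C = CK / K;
    const int padL = (K - 1) / 2;
    const R_xlen_t BL = (R_xlen_t) B * L;
    const double one = 1.0;

    SEXP dA_ = PROTECT(Rf_allocMatrix(REALSXP, C, (int) BL));
    double *dA = REAL(dA_);
    memset(dA, 0, (size_t) C * BL * sizeof(double));

    for (int k = 0; k < K; k++) {
        const int sh = k - padL;
        const int l0 = sh > 0 ? 0 : -sh;
        const int l1 = sh > 0 ? L - sh : L;
        if (l1 <= l0) continue;
        const int len = l1 - l0;
        for (int b = 0; b < B; b++) {
            const R_xlen_t base = (R_xlen_t) b * L;
            F77_CALL(dgemm)("N", "N", &C, &len, &F, &one,
                            W + (R_xlen_t) k * C, &CK,
                            dOut + (base + l0) * F, &F, &one,
                            dA + (base + l0 + sh) * C, &C
                            FCONE FCONE);
        }
    }
    UNPROTECT(1);
    return dA_;
}

/* Weight gradient: gW_k (C x F) = A_(shifted k) dOut^T. */
SEXP C_conv1d_bwd_weights(SEXP A_, SEXP dOut_, SEXP B_, SEXP L_,
                          SEXP K_)
{
    const double *A = REAL(A_);
    const double *dOut = REAL(dOut_);
    const int C = Rf_nrows(A_);
    const int F = Rf_nrows(dOut_);
    const int B = Rf_asInteger(B_);
    const int L = Rf_asInteger(L_);
    const int K = Rf_asInteger(K_);
    const int CK = C * K;
    const int padL = (K - 1) / 2;
    const double one = 1.0;

    SEXP gW_ = PROTECT(Rf_allocMatrix(REALSXP, CK, F));
    double *gW = REAL(gW_);
    memset(gW, 0, (size_t) CK * F * sizeof(double));

    for (int k = 0; k < K; k++) {
        const int sh = k - padL;
        const int l0 = sh > 0 ? 0 : -sh;
        const int l1 = sh > 0 ? L - sh : L;
        if (l1 <= l0) continue;
        const int len = l1 - l0;
        for (int b = 0; b < B; b++) {
            const R_xlen_t base = (R_xlen_t) b * L;
            F77_CALL(dgemm)("N", "T", &C, &F, &len, &one,
                            A + (base + l0 + sh) * C, &C,
                            dOut + (base + l0) * F, &F, &one,
                            gW + (R_xlen_t) k * C, &CK
                            FCONE FCONE);
        }
    }
    UNPROTECT(1);
    return gW_;
}
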