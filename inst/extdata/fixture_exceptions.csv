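table,setting,rank,code,printed_group,scheme_group,note
post,secondary,66,I31.9,cardiac,peripheral_vascular,"I31.9 is printed under cardiac (subcategory f, other) in the post-index hospital list but under peripheral or other vascular in the pre-index hospital list; the scheme follows the pre-index placement"
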