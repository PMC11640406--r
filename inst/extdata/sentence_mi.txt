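AVLV1SV2SAVRAVRLd2Ld2AVLV3AV4AV6LV4AV5LLd1V3AV1SV2SV2SV5LV3AV4AV2SV4ALd1V6LV3ALd1V5LLd3AVFAVFLd1AVFV2SLd1Ld2V6LV6LAVLV4AAVRAVFLd2V4AV4AV4AV4AAVRV1SLd2Ld1V3AAVLV2SV3AV6LV2SV3AV6LAVRV1SLd3AVRAVRV5LV1SV5LV2SAVLLd3AVRV4ALd1V2SAVLAVLLd2Ld2AVFV1SLd2V2SLd3AVRV2SAVLLd3V2SLd2V5LV5LAVRV3AV5LLd1AVFLd2AVRAVRV1SAVFLd3V6LV1SLd3V6LV1SV4ALd1AVRV3AAVRLd1Ld1V6LAVLV3AAVLV3ALd2V3ALd1V3AV3AAVRV3AAVRV2SV5LLd2V4AV6LLd2V6LLd1AVLV4AAVLAVFLd2V4AV5LAVLLd2V5LAVFV1SV1SLd1Ld3V5LV5LV6LLd1V4ALd3AVFAVRLd3V4AV2SLd3Ld3Ld3AVLV3AV1SLd1V3AAVFAVLV6LV6LLd2V1SV2SLd2V1SLd2V3AAVFV5LAVLV5LV1SV5LV4AAVFV1SAVRV1SV3AV1SV6L
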